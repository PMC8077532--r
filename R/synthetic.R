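#' Chronotype specification for the trajectory generator
#'
#' Describes the behavioural repertoire of one synthetic animal: a two-state
#' (rest/swim) alternating-renewal process whose per-phase swim fractions
#' are tilted to achieve a target activity change ratio, with lognormal swim
#' speeds, exponential rest bouts above a configurable minimum (so some
#' sub-threshold inactivity exists to exercise the strict 60 s rule),
#' Gaussian tracking noise and random frame dropout.
#'
#' @param diurnality target activity change ratio in `[-1, 1]`.
#' @param rest_fraction proportion of the recording spent in the rest state,
#'   in `[0, 1)`.
#' @param waking_speed_mean,waking_speed_sd lognormal swim-speed mean and sd
#'   (cm/s); the mean must exceed the activity threshold.
#' @param rest_bout_mean,rest_bout_min mean and minimum of rest-bout
#'   durations (s); durations are `min + Exponential(mean - min)`.
#' @param pp a [photoperiod()].
#' @param tracking_noise_sd positional noise sd (cm), applied last.
#' @param dropout_rate fraction of frames with no fix.
#' @param activity_threshold speed threshold (cm/s) used for the generator's
#'   ground-truth bookkeeping.
#' @return a `cf_chronotype` list.
#' @export
chronotype_spec <- function(diurnality = 0, rest_fraction = 0.3,
                            waking_speed_mean = 8, waking_speed_sd = 3,
                            rest_bout_mean = 120, rest_bout_min = 20,
                            pp = photoperiod(), tracking_noise_sd = 0,
                            dropout_rate = 0, activity_threshold = 4) {
  if (rest_fraction < 0 || rest_fraction >= 1) {
    abort("rest_fraction must lie in [0, 1)")
  }
  if (abs(diurnality) > 1) abort("diurnality must lie in [-1, 1]")
  if (waking_speed_mean <= activity_threshold) {
    abort("waking_speed_mean must exceed the activity threshold")
  }
  if (rest_bout_min < 0 || rest_bout_mean <= rest_bout_min) {
    abort("need 0 <= rest_bout_min < rest_bout_mean")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate in [0, 1)")
  structure(list(diurnality = diurnality, rest_fraction = rest_fraction,
                 waking_speed_mean = waking_speed_mean,
                 waking_speed_sd = waking_speed_sd,
                 rest_bout_mean = rest_bout_mean,
                 rest_bout_min = rest_bout_min, pp = pp,
                 tracking_noise_sd = tracking_noise_sd,
                 dropout_rate = dropout_rate,
                 activity_threshold = activity_threshold),
            class = "cf_chronotype")
}

# reflective boundary by triangle-wave folding of the unbounded coordinate
.fold <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

# per-phase swim fractions achieving the diurnality target at the given
# total rest fraction, under a day_h:night_h photoperiod
.phase_swim_fractions <- function(diurnality, rest_fraction, pp) {
  day_h <- pp$lights_off - pp$lights_on
  night_h <- pp$cycle_length - day_h
  # a_day = c(1+A), a_night = c(1-A); weighted mean equals 1 - rest_fraction
  cval <- pp$cycle_length * (1 - rest_fraction) /
    (day_h * (1 + diurnality) + night_h * (1 - diurnality))
  a <- c(day = cval * (1 + diurnality), night = cval * (1 - diurnality))
  if (any(a > 1 + 1e-9)) {
    abort(paste0("infeasible chronotype: required swim fraction ",
                 sprintf("%.3f", max(a)), " exceeds 1; lower rest_fraction ",
                 "or diurnality magnitude"))
  }
  pmin(a, 1)
}

#' Generate a synthetic 24 h trajectory with ground truth
#'
#' Simulates an alternating rest/swim renewal process (per-phase swim
#' fractions tilted to the diurnality target), renders swimming as a bounded
#' correlated random walk in the arena, records ground-truth bookkeeping
#' (true rest bouts, active distance, waking velocity, day/night activity
#' and shelter occupancy) from the noise-free positions, and only then
#' applies tracking noise and dropout.
#'
#' @param spec a [chronotype_spec()].
#' @param duration_h recording length, h.
#' @param frame_rate frames per second.
#' @param start_zt zeitgeber hours at recording start.
#' @param arena arena size `c(width_cm, height_cm)`.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @param animal_id,species,lineage_group metadata for the trajectory.
#' @param shelter optional `cf_zone`; occupancy ground truth is recorded when
#'   present.
#' @param turn_sd sd of per-frame heading increments (radians).
#' @return list with `trajectory` (a `cf_trajectory`, noise and dropout
#'   applied) and `truth` (list of ground-truth metrics from the latent
#'   noise-free path).
#' @export
generate_trajectory <- function(spec, duration_h = 24, frame_rate = 15,
                                start_zt = 3, arena = c(30, 20), seed,
                                animal_id = "synthetic", species = "synthetic",
                                lineage_group = NA_character_, shelter = NULL,
                                turn_sd = 0.3) {
  stopifnot(inherits(spec, "cf_chronotype"))
  if (missing(seed)) abort("generate_trajectory requires a seed")
  set.seed(seed)
  pp <- spec$pp
  fr <- frame_rate
  dur_s <- duration_h * 3600
  a_phase <- .phase_swim_fractions(spec$diurnality, spec$rest_fraction, pp)

  # phase segments of the recording: split at every lights_on/off crossing
  cyc_s <- pp$cycle_length * 3600
  crossings <- function(zt_h) {
    t0 <- (zt_h - start_zt) * 3600
    ks <- ceiling((0 - t0) / cyc_s):floor((dur_s - t0) / cyc_s)
    t0 + ks * cyc_s
  }
  bounds <- sort(unique(pmin(pmax(
    c(0, dur_s, crossings(pp$lights_on), crossings(pp$lights_off)), 0), dur_s)))

  # alternating-renewal state intervals; state TRUE = swim
  seg_starts <- head(bounds, -1)
  seg_ends <- tail(bounds, -1)
  iv_start <- numeric(0)
  iv_state <- logical(0)
  draw_rest <- function() spec$rest_bout_min +
    rexp(1, 1 / (spec$rest_bout_mean - spec$rest_bout_min))
  for (s in seq_along(seg_starts)) {
    t <- seg_starts[s]
    mid_zt <- start_zt + (seg_starts[s] + seg_ends[s]) / 2 / 3600
    a <- if (is_day(mid_zt, pp)) a_phase[["day"]] else a_phase[["night"]]
    if (a <= 0 || a >= 1) {
      # degenerate phase: entirely at rest or entirely swimming
      iv_start <- c(iv_start, t)
      iv_state <- c(iv_state, a >= 1)
      next
    }
    mean_swim <- spec$rest_bout_mean * a / (1 - a)
    swimming <- runif(1) < a
    while (t < seg_ends[s]) {
      d <- if (swimming) rexp(1, 1 / mean_swim) else draw_rest()
      iv_start <- c(iv_start, t)
      iv_state <- c(iv_state, swimming)
      t <- t + d
      swimming <- !swimming
    }
  }

  n <- as.integer(round(dur_s * fr)) + 1L
  time_s <- (seq_len(n) - 1L) / fr
  swim <- iv_state[findInterval(time_s, iv_start)]

  # correlated random walk while swimming; stationary while resting
  sdlog <- sqrt(log(1 + (spec$waking_speed_sd / spec$waking_speed_mean)^2))
  meanlog <- log(spec$waking_speed_mean) - sdlog^2 / 2
  step_speed <- numeric(n)
  step_speed[swim] <- rlnorm(sum(swim), meanlog, sdlog)
  heading <- cumsum(rnorm(n, 0, turn_sd)) + runif(1, 0, 2 * pi)
  dx <- c(0, (step_speed * cos(heading) / fr)[-n])
  dy <- c(0, (step_speed * sin(heading) / fr)[-n])
  x <- .fold(arena[1] / 2 + cumsum(dx), arena[1])
  y <- .fold(arena[2] / 2 + cumsum(dy), arena[2])

  # ground-truth bookkeeping from the latent noise-free path
  d_frame <- sqrt(diff(x)^2 + diff(y)^2)
  sp_frame <- d_frame * fr
  active <- sp_frame > spec$activity_threshold
  r <- rle(!active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rest_keep <- r$values & (r$lengths / fr > 60)
  true_bouts <- tibble(start_s = (starts[rest_keep] - 1) / fr,
                       duration_s = r$lengths[rest_keep] / fr)
  mid_t <- (time_s[-n] + time_s[-1]) / 2
  day_iv <- is_day(start_zt + mid_t / 3600, pp)
  day_cov_h <- sum(day_iv) / fr / 3600
  night_cov_h <- sum(!day_iv) / fr / 3600
  D <- sum(d_frame[active & day_iv]) / day_cov_h
  N <- sum(d_frame[active & !day_iv]) / night_cov_h
  truth <- list(
    total_activity_cm = sum(d_frame[active]),
    waking_velocity_cms = if (any(active)) mean(sp_frame[active]) else NA_real_,
    total_rest_h = sum(true_bouts$duration_s) / 3600,
    bouts = true_bouts,
    D = D, N = N,
    A_R = activity_change_ratio(D, N),
    swim_state_fraction = mean(swim)
  )
  if (!is.null(shelter)) {
    inside <- in_zone(shelter, x, y)
    day_f <- is_day(start_zt + time_s / 3600, pp)
    truth$occupancy_total <- mean(inside)
    truth$occupancy_day <- mean(inside[day_f])
    truth$occupancy_night <- mean(inside[!day_f])
  }

  # observation model: noise then dropout
  if (spec$tracking_noise_sd > 0) {
    x <- x + rnorm(n, 0, spec$tracking_noise_sd)
    y <- y + rnorm(n, 0, spec$tracking_noise_sd)
  }
  if (spec$dropout_rate > 0) {
    drop <- runif(n) < spec$dropout_rate
    x[drop] <- NA_real_
    y[drop] <- NA_real_
  }
  traj <- trajectory(tibble(time_s = time_s, x = x, y = y),
                     animal_id = animal_id, species = species,
                     lineage_group = lineage_group, frame_rate = fr,
                     start_zt = start_zt, arena = arena)
  list(trajectory = traj, truth = truth)
}

#' Generate an ultrametric pure-birth tree
#'
#' A Yule tree on `n_tips` tips, rescaled to unit root-to-tip depth.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @return a `phylo` with tip labels `s1..sn`.
#' @export
generate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) abort("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("s", seq_len(n_tips))
  tree
}

#' Generate predictor/response trait data on a tree
#'
#' The predictor evolves under Brownian motion; the response is
#' `intercept + slope * predictor` plus an error drawn from a multivariate
#' normal whose covariance is the lambda-transformed tree covariance scaled
#' by `noise_rate`. With `noise_rate = 0` the regression is exact; with
#' `lambda_true = 0` the errors are independent across taxa.
#'
#' @param tree rooted `phylo`.
#' @param slope,intercept regression coefficients.
#' @param lambda_true Pagel's lambda of the error covariance, in `[0, 1]`.
#' @param noise_rate error variance scale.
#' @param predictor_rate Brownian rate of the predictor.
#' @param seed optional integer seed.
#' @return tibble: `taxon`, `x`, `y`.
#' @export
generate_traits <- function(tree, slope = 2, intercept = 0, lambda_true = 1,
                            noise_rate = 1, predictor_rate = 1, seed = NULL) {
  if (lambda_true < 0 || lambda_true > 1) abort("lambda_true in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  x <- simulate_bm(tree, rate = predictor_rate, n_sims = 1)[, 1]
  V <- lambda_transform(phylo_vcv(tree), lambda_true)
  n <- nrow(V)
  e <- if (noise_rate > 0) {
    R <- chol(V)
    sqrt(noise_rate) * as.numeric(crossprod(R, rnorm(n)))
  } else {
    rep(0, n)
  }
  tibble(taxon = tree$tip.label, x = unname(x),
         y = intercept + slope * unname(x) + e)
}

#' Write a synthetic fixture set to disk
#'
#' Writes the tracking-table CSV in the dialect [read_tracking_table()]
#' expects plus a ground-truth JSON next to it.
#'
#' @param sim result of [generate_trajectory()].
#' @param dir output directory (created if needed).
#' @param name fixture basename.
#' @return named character vector of paths, invisibly.
#' @export
write_fixture <- function(sim, dir, name = attr(sim$trajectory, "animal_id")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, "_truth.json"))
  write_tracking_table(sim$trajectory, csv)
  truth <- sim$truth
  truth$bouts <- NULL
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tracking = csv, truth = js))
}
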