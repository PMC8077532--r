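#' Photoperiod description
#'
#' The entrained light regime: lights-on at `lights_on` (ZT0 by convention)
#' and lights-off at `lights_off` zeitgeber hours, within a cycle of
#' `cycle_length` hours. Under `regime = "constant_dark"` the same boundaries
#' label *subjective* day and night inherited from the prior entrained cycle.
#'
#' @param lights_on,lights_off zeitgeber hours, `0 <= on < off <= cycle`.
#' @param cycle_length cycle length in hours.
#' @param regime `"light_dark"` or `"constant_dark"`.
#' @return a `cf_photoperiod` list.
#' @export
photoperiod <- function(lights_on = 0, lights_off = 14, cycle_length = 24,
                        regime = c("light_dark", "constant_dark")) {
  regime <- match.arg(regime)
  if (!(lights_on >= 0 && lights_on < lights_off && lights_off <= cycle_length)) {
    abort("need 0 <= lights_on < lights_off <= cycle_length")
  }
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 cycle_length = cycle_length, regime = regime),
            class = "cf_photoperiod")
}

#' Is a zeitgeber time in the (subjective) day phase?
#' @param zt zeitgeber hours (any real; reduced modulo the cycle).
#' @param pp a [photoperiod()].
#' @return logical vector.
#' @export
is_day <- function(zt, pp = photoperiod()) {
  z <- zt %% pp$cycle_length
  z >= pp$lights_on & z < pp$lights_off
}

#' Bin a time series into zeitgeber-aligned hourly bins
#'
#' Accumulates per-interval amounts (e.g. centimetres swum per frame
#' interval, or seconds of rest) into 1 h bins aligned to zeitgeber time,
#' wrapping modulo 24. Each bin's total is normalised by the recording time
#' that fell in the bin, so partially covered bins report a per-hour rate
#' rather than an artificially low total.
#'
#' @param series data frame with `time_s` (seconds since recording start),
#'   `value` (amount attributed to the sample) and optionally `dt` (interval
#'   length, s; defaults to the median spacing).
#' @param start_zt zeitgeber hours at recording start.
#' @param cycle_length hours per cycle (bins `0:(cycle_length-1)`).
#' @return a `cf_hourly` tibble: `zt` (bin start, h), `total` (summed
#'   amount), `coverage_h` (recording hours in the bin) and `value`
#'   (per-hour rate = total / coverage).
#' @export
bin_hourly <- function(series, start_zt, cycle_length = 24) {
  stopifnot(is.data.frame(series), all(c("time_s", "value") %in% names(series)))
  if (nrow(series) == 0) abort("empty series: nothing to bin")
  span_h <- diff(range(series$time_s)) / 3600
  if (span_h > cycle_length) {
    abort("series spans more than one cycle; bin per cycle before calling")
  }
  dt <- series$dt %||% rep(median(diff(sort(series$time_s))), nrow(series))
  zt <- (start_zt + series$time_s / 3600) %% cycle_length
  bin <- floor(zt)
  zt_bins <- 0:(cycle_length - 1)
  fbin <- factor(bin, levels = zt_bins)
  total <- as.numeric(tapply(series$value, fbin, sum))
  coverage <- as.numeric(tapply(dt, fbin, sum)) / 3600
  total[is.na(total)] <- 0
  coverage[is.na(coverage)] <- 0
  out <- tibble(zt = zt_bins, total = total, coverage_h = coverage,
                value = ifelse(coverage > 0, total / coverage, NA_real_))
  structure(out, class = c("cf_hourly", class(out)), start_zt = start_zt)
}

#' Hourly activity profile of one animal
#'
#' Distance travelled during active intervals, binned to ZT hours
#' (cm per hour).
#'
#' @param speeds a classified speed series ([classify_activity()]).
#' @return a `cf_hourly` tibble.
#' @export
activity_profile <- function(speeds) {
  act <- !is.na(speeds$active) & speeds$active
  ser <- tibble(time_s = speeds$time_s,
                value = ifelse(act, speeds$speed * speeds$dt, 0),
                dt = speeds$dt)
  bin_hourly(ser, start_zt = attr(speeds, "start_zt") %||% 0)
}

#' Phase-wise mean hourly activity
#'
#' Day (`D`) and night (`N`) mean hourly activity: bin totals summed within
#' each phase and divided by the recording hours in that phase, so the 14 h
#' day and 10 h night are comparable.
#'
#' @param profile a `cf_hourly` profile from [bin_hourly()].
#' @param pp a [photoperiod()]; must be the entrained `light_dark` regime
#'   (for constant-dark recordings use [subjective_day_night()]).
#' @return one-row tibble with `D`, `N` and `A_R` (see
#'   [activity_change_ratio()]).
#' @export
day_night_means <- function(profile, pp = photoperiod()) {
  if (pp$regime != "light_dark") {
    abort(paste0("day_night_means needs an entrained light:dark photoperiod; ",
                 "for constant-dark recordings use subjective_day_night()"))
  }
  .phase_means(profile, pp)
}

#' Subjective-phase mean hourly activity under constant darkness
#'
#' Identical computation to [day_night_means()] but against the subjective
#' day/night labels inherited from the prior entrained cycle; the resulting
#' ratio is a subjective-phase ratio and outputs are labelled accordingly.
#'
#' @inheritParams day_night_means
#' @return one-row tibble with `D`, `N`, `A_R` and `phase_labels =
#'   "subjective"`.
#' @export
subjective_day_night <- function(profile, pp = photoperiod(regime = "constant_dark")) {
  out <- .phase_means(profile, pp)
  out$phase_labels <- "subjective"
  out
}

.phase_means <- function(profile, pp) {
  stopifnot(is.data.frame(profile),
            all(c("zt", "total", "coverage_h") %in% names(profile)))
  day <- is_day(profile$zt + 0.5, pp)
  d_cov <- sum(profile$coverage_h[day])
  n_cov <- sum(profile$coverage_h[!day])
  D <- if (d_cov > 0) sum(profile$total[day]) / d_cov else NA_real_
  N <- if (n_cov > 0) sum(profile$total[!day]) / n_cov else NA_real_
  tibble(D = D, N = N, A_R = activity_change_ratio(D, N))
}

#' Activity change ratio
#'
#' The dimensionless day/night preference index `(D - N) / (D + N)`: +1 for
#' an exclusively day-active animal, -1 for an exclusively night-active one,
#' 0 when day and night activity are equal. Undefined (returned as `NA`)
#' when `D + N = 0`.
#'
#' @param D,N non-negative mean hourly activity in the day and night phases.
#'   `D` may also be a one-row data frame holding columns `D` and `N`.
#' @return numeric in `[-1, 1]`, or `NA`.
#' @export
activity_change_ratio <- function(D, N = NULL) {
  if (is.data.frame(D)) {
    N <- D$N
    D <- D$D
  }
  if (any(D < 0, na.rm = TRUE) || any(N < 0, na.rm = TRUE)) {
    abort("D and N must be non-negative")
  }
  s <- D + N
  ifelse(is.na(s) | s == 0, NA_real_, (D - N) / s)
}

#' Apportion rest bouts to day and night
#'
#' Each bout's duration is split across the phases it overlaps in proportion
#' to overlap (not assigned to its start phase), then phase totals are
#' divided by the recording time spent in each phase, giving rest rates in
#' minutes per hour.
#'
#' @param bouts tibble from [detect_rest_bouts()].
#' @param start_zt zeitgeber hours at recording start.
#' @param duration_s total recording duration, s.
#' @param pp a [photoperiod()].
#' @return one-row tibble: `rest_day_min_per_h`, `rest_night_min_per_h`,
#'   `rest_day_h`, `rest_night_h`, `day_coverage_h`, `night_coverage_h`.
#' @export
rest_day_night <- function(bouts, start_zt, duration_s, pp = photoperiod()) {
  day_overlap_s <- function(t0, t1) {
    # integrate the day-phase indicator over [t0, t1] (absolute seconds);
    # split at every phase boundary crossed
    z0 <- start_zt + t0 / 3600
    z1 <- start_zt + t1 / 3600
    cyc <- pp$cycle_length
    k <- floor(z0 / cyc):ceiling(z1 / cyc)
    bounds <- sort(unique(c(z0, z1,
                            outer(k * cyc, c(pp$lights_on, pp$lights_off), "+"))))
    bounds <- bounds[bounds >= z0 & bounds <= z1]
    if (length(bounds) < 2) return(0)
    mid <- (head(bounds, -1) + tail(bounds, -1)) / 2
    sum(diff(bounds)[is_day(mid, pp)]) * 3600
  }
  day_rest <- if (nrow(bouts) > 0) {
    sum(map_dbl(seq_len(nrow(bouts)), function(i) {
      day_overlap_s(bouts$start_s[i], bouts$start_s[i] + bouts$duration_s[i])
    }))
  } else 0
  night_rest <- sum(bouts$duration_s) - day_rest
  day_cov <- day_overlap_s(0, duration_s)
  night_cov <- duration_s - day_cov
  tibble(
    rest_day_min_per_h = if (day_cov > 0) (day_rest / 60) / (day_cov / 3600) else NA_real_,
    rest_night_min_per_h = if (night_cov > 0) (night_rest / 60) / (night_cov / 3600) else NA_real_,
    rest_day_h = day_rest / 3600,
    rest_night_h = night_rest / 3600,
    day_coverage_h = day_cov / 3600,
    night_coverage_h = night_cov / 3600
  )
}

#' Shelter zone constructors
#'
#' A shelter zone is a rectangle or circle in arena centimetres.
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (cm).
#' @return a `cf_zone` list.
#' @export
zone_rect <- function(xmin, xmax, ymin, ymax) {
  if (!(xmax > xmin && ymax > ymin)) abort("degenerate (zero-area) zone")
  structure(list(type = "rect", xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax), class = "cf_zone")
}

#' @rdname zone_rect
#' @param x,y,r circle centre and radius (cm).
#' @export
zone_circle <- function(x, y, r) {
  if (!(r > 0)) abort("degenerate (zero-area) zone")
  structure(list(type = "circle", x = x, y = y, r = r), class = "cf_zone")
}

#' Is a point inside a zone?
#' @param zone a `cf_zone`.
#' @param x,y coordinates (cm).
#' @return logical vector.
#' @export
in_zone <- function(zone, x, y) {
  stopifnot(inherits(zone, "cf_zone"))
  if (zone$type == "rect") {
    x >= zone$xmin & x <= zone$xmax & y >= zone$ymin & y <= zone$ymax
  } else {
    (x - zone$x)^2 + (y - zone$y)^2 <= zone$r^2
  }
}

#' Shelter occupancy fractions
#'
#' Fraction of non-missing frames whose centroid lies inside the shelter
#' zone, overall and per photoperiod phase. No dwell-time hysteresis is
#' applied: occupancy is per-frame centroid-in-zone.
#'
#' @param traj a `cf_trajectory`.
#' @param zone a `cf_zone` ([zone_rect()] or [zone_circle()]).
#' @param pp a [photoperiod()].
#' @return one-row tibble: `occupancy_total`, `occupancy_day`,
#'   `occupancy_night`, `n_frames_used`.
#' @export
shelter_occupancy <- function(traj, zone, pp = photoperiod()) {
  stopifnot(inherits(traj, "cf_trajectory"), inherits(zone, "cf_zone"))
  arena <- attr(traj, "arena")
  if (!is.null(arena)) {
    ok_bounds <- if (zone$type == "rect") {
      zone$xmin >= 0 && zone$ymin >= 0 && zone$xmax <= arena[1] && zone$ymax <= arena[2]
    } else {
      zone$x - zone$r >= 0 && zone$y - zone$r >= 0 &&
        zone$x + zone$r <= arena[1] && zone$y + zone$r <= arena[2]
    }
    if (!ok_bounds) abort("shelter zone extends outside the arena bounds")
  }
  ok <- !is.na(traj$x) & !is.na(traj$y)
  if (!any(ok)) abort("all frames missing: no positional data")
  inside <- in_zone(zone, traj$x[ok], traj$y[ok])
  zt <- attr(traj, "start_zt") + traj$time_s[ok] / 3600
  day <- is_day(zt, pp)
  frac <- function(sel) if (any(sel)) mean(inside[sel]) else NA_real_
  tibble(occupancy_total = mean(inside),
         occupancy_day = frac(day),
         occupancy_night = frac(!day),
         n_frames_used = sum(ok))
}

#' Circadian metrics for one scored animal
#'
#' Bundles the hourly activity profile, D/N means, activity change ratio,
#' day/night rest rates and (optionally) shelter occupancy into one row.
#'
#' @param scored result of [score_animal()].
#' @param traj the trajectory the scores came from (needed for shelter
#'   occupancy).
#' @param pp a [photoperiod()].
#' @param zone optional `cf_zone`.
#' @return one-row tibble of circadian metrics. Under a `constant_dark`
#'   photoperiod D/N are subjective-phase values and the column
#'   `phase_labels` says so.
#' @export
circadian_metrics <- function(scored, traj = NULL, pp = photoperiod(),
                              zone = NULL) {
  speeds <- scored$speeds
  prof <- activity_profile(speeds)
  dn <- if (pp$regime == "light_dark") {
    dplyr::mutate(day_night_means(prof, pp), phase_labels = "entrained")
  } else {
    subjective_day_night(prof, pp)
  }
  rest <- rest_day_night(scored$bouts, attr(speeds, "start_zt") %||% 0,
                         attr(speeds, "duration_s") %||% sum(speeds$dt), pp)
  out <- dplyr::bind_cols(
    tibble(animal_id = attr(speeds, "animal_id") %||% NA_character_,
           species = attr(speeds, "species") %||% NA_character_,
           lineage_group = attr(speeds, "lineage_group") %||% NA_character_),
    dn, rest)
  if (!is.null(zone)) {
    if (is.null(traj)) abort("shelter occupancy needs the trajectory")
    out <- dplyr::bind_cols(out, shelter_occupancy(traj, zone, pp))
  }
  out
}
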