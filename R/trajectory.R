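#' Construct a trajectory object
#'
#' A trajectory is a tibble of per-frame fixes (`frame`, `time_s`, `x`, `y`)
#' with animal-level metadata stored as attributes. Positions are in arena
#' centimetres; frames the tracker failed to resolve are kept as rows with
#' `NA` coordinates rather than dropped, so downstream gap handling is
#' explicit.
#'
#' @param data data frame with columns `time_s`, `x`, `y` (and optionally
#'   `frame`). Times are seconds since recording start and must be strictly
#'   increasing at an approximately constant frame interval.
#' @param animal_id identifier for the individual.
#' @param species species label (used as the taxon key downstream).
#' @param lineage_group lineage label, e.g. `"mbuna"` or `"non_mbuna"`.
#' @param frame_rate frames per second. If `NULL`, inferred from the median
#'   inter-frame interval.
#' @param start_zt zeitgeber time (hours, in `[0, 24)`) of the first frame.
#' @param arena optional arena size `c(width_cm, height_cm)`.
#' @return a `cf_trajectory` tibble.
#' @export
trajectory <- function(data, animal_id, species = NA_character_,
                       lineage_group = NA_character_, frame_rate = NULL,
                       start_zt = 3, arena = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("time_s", "x", "y")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data[, intersect(c("frame", need), names(data))])
  if (!"frame" %in% names(out)) out$frame <- seq_len(nrow(out))
  out <- out[, c("frame", "time_s", "x", "y")]

  if (nrow(out) < 1) abort("trajectory has no frames")
  dt <- diff(out$time_s)
  if (any(dt <= 0)) {
    abort(paste0("timestamps not strictly increasing at row ",
                 which(dt <= 0)[1] + 1))
  }
  if (!is.null(frame_rate)) {
    if (length(dt) > 0 && any(abs(dt - 1 / frame_rate) > 0.25 / frame_rate)) {
      warn("inter-frame spacing deviates from 1/frame_rate by more than 25%")
    }
  } else {
    frame_rate <- if (length(dt) > 0) 1 / median(dt) else 1
  }
  if (is.na(start_zt) || start_zt < 0 || start_zt >= 24) {
    abort("start_zt must lie in [0, 24)")
  }
  bad <- !is.na(out$x) & !is.na(out$y) & (!is.finite(out$x) | !is.finite(out$y))
  if (any(bad)) abort("non-finite positions in non-missing frames")

  structure(out,
            class = c("cf_trajectory", class(out)),
            animal_id = animal_id, species = species,
            lineage_group = lineage_group, frame_rate = frame_rate,
            start_zt = start_zt, arena = arena)
}

#' Frame indices with no positional fix
#' @param traj a `cf_trajectory`.
#' @return integer vector of frame indices where x or y is missing.
#' @export
missing_frames <- function(traj) {
  which(is.na(traj$x) | is.na(traj$y))
}

#' @export
print.cf_trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s (%s, %s): %d frames @ %.3g fps, start ZT%.1f, %d missing\n",
    attr(x, "animal_id"), attr(x, "species") %||% NA,
    attr(x, "lineage_group") %||% NA, nrow(x), attr(x, "frame_rate"),
    attr(x, "start_zt"), length(missing_frames(x))))
  NextMethod()
}

#' Read a tracker-export positional table
#'
#' Reads a delimited table of per-frame fixes (time, x, y columns; dialect
#' configurable), applies the arena calibration, and returns a validated
#' [trajectory()]. Rows where the tracker lost the animal (blank or
#' non-numeric x/y) become missing frames; they are recorded, never dropped.
#'
#' @param path file path.
#' @param calibration centimetres per tracker unit (must be > 0).
#' @param animal_id,species,lineage_group,start_zt,frame_rate,arena metadata
#'   passed to [trajectory()].
#' @param col_names named character vector mapping the roles `time`, `x`, `y`
#'   to column names in the file.
#' @param delim field delimiter.
#' @return a `cf_trajectory`.
#' @export
read_tracking_table <- function(path, calibration = 1, animal_id = basename(path),
                                species = NA_character_,
                                lineage_group = NA_character_,
                                start_zt = 3, frame_rate = NULL, arena = NULL,
                                col_names = c(time = "time", x = "x", y = "y"),
                                delim = ",") {
  if (!is.numeric(calibration) || calibration <= 0) {
    abort("calibration must be a positive scale (cm per tracker unit)")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(col_names[c("time", "x", "y")]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("tracking table ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  t_raw <- raw[[col_names[["time"]]]]
  t_num <- suppressWarnings(as.numeric(t_raw))
  bad_t <- which(is.na(t_num) & !(is.na(t_raw) | trimws(t_raw) == ""))
  if (length(bad_t) > 0) {
    abort(paste0("malformed time value at data line ", bad_t[1], " of ", path))
  }
  if (anyNA(t_num)) {
    abort(paste0("missing time value at data line ", which(is.na(t_num))[1],
                 " of ", path))
  }
  num_or_na <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    # blank / "-" / "NA" entries are lost fixes, anything else non-numeric is a
    # parse error worth naming
    bad <- which(is.na(out) & !is.na(v) &
                   !(trimws(v) %in% c("", "-", "NA", "NaN", "nan")))
    if (length(bad) > 0) {
      abort(paste0("malformed ", what, " value '", v[bad[1]],
                   "' at data line ", bad[1], " of ", path))
    }
    out
  }
  x <- num_or_na(raw[[col_names[["x"]]]], "x") * calibration
  y <- num_or_na(raw[[col_names[["y"]]]], "y") * calibration
  if (any(diff(t_num) <= 0)) {
    abort(paste0("timestamps not monotone increasing at data line ",
                 which(diff(t_num) <= 0)[1] + 1, " of ", path))
  }
  trajectory(tibble(time_s = t_num, x = x, y = y),
             animal_id = animal_id, species = species,
             lineage_group = lineage_group, frame_rate = frame_rate,
             start_zt = start_zt, arena = arena)
}

#' Write a trajectory as a tracking table
#'
#' Inverse of [read_tracking_table()] (at calibration 1): writes `time`, `x`,
#' `y` columns, missing fixes as blank fields.
#'
#' @param traj a `cf_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(traj, path) {
  readr::write_csv(tibble(time = traj$time_s, x = traj$x, y = traj$y),
                   path, na = "")
  invisible(path)
}

#' Per-interval swimming speed
#'
#' Converts per-frame positions into speeds over each inter-frame interval:
#' Euclidean displacement divided by the frame interval. Tracking gaps no
#' longer than `max_gap` seconds are filled by linear interpolation of the
#' positions; longer gaps yield undefined intervals (`NA` speed) that are
#' excluded from activity classification and break rest runs.
#'
#' @param traj a `cf_trajectory`.
#' @param max_gap maximum dropout length (s) to interpolate across.
#' @param smooth_width width (odd number of intervals) of an optional centred
#'   moving-median applied to the speed series; 1 (the default) disables
#'   smoothing. Smoothing is applied within contiguous defined stretches only.
#' @return a speed-series tibble with columns `time_s` (interval midpoint),
#'   `dt` (interval length, s) and `speed` (cm/s); frame rate and metadata are
#'   carried in attributes.
#' @export
compute_speed <- function(traj, max_gap = 2, smooth_width = 1) {
  stopifnot(inherits(traj, "cf_trajectory"))
  fr <- attr(traj, "frame_rate")
  ok <- !is.na(traj$x) & !is.na(traj$y)
  if (sum(ok) == 0) abort("all frames missing: no positional data")
  if (sum(ok) < 2) abort("need at least 2 non-missing frames")

  x <- traj$x
  y <- traj$y
  miss <- !ok
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    fill <- rep(FALSE, length(miss))
    for (i in seq_along(r$lengths)) {
      if (r$values[i] && r$lengths[i] / fr <= max_gap) {
        fill[starts[i]:ends[i]] <- TRUE
      }
    }
    # interpolate everything, then un-fill the long gaps (and leading/trailing
    # runs, which approx leaves NA anyway)
    xi <- approx(traj$time_s[ok], x[ok], xout = traj$time_s, rule = 1)$y
    yi <- approx(traj$time_s[ok], y[ok], xout = traj$time_s, rule = 1)$y
    x[fill] <- xi[fill]
    y[fill] <- yi[fill]
  }
  n <- nrow(traj)
  dx <- diff(x)
  dy <- diff(y)
  dt <- diff(traj$time_s)
  speed <- sqrt(dx^2 + dy^2) / dt
  if (smooth_width > 1) {
    if (smooth_width %% 2 == 0) abort("smooth_width must be odd")
    speed <- local({
      s <- speed
      r <- rle(!is.na(s))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in seq_along(r$lengths)) {
        if (r$values[i] && r$lengths[i] >= smooth_width) {
          idx <- starts[i]:ends[i]
          s[idx] <- stats::runmed(s[idx], smooth_width, endrule = "keep")
        }
      }
      s
    })
  }
  out <- tibble(time_s = (traj$time_s[-n] + traj$time_s[-1]) / 2,
                dt = dt, speed = speed)
  structure(out,
            class = c("cf_speed", class(out)),
            animal_id = attr(traj, "animal_id"),
            species = attr(traj, "species"),
            lineage_group = attr(traj, "lineage_group"),
            frame_rate = fr,
            start_zt = attr(traj, "start_zt"),
            duration_s = traj$time_s[n] - traj$time_s[1])
}

#' Classify active swimming by a velocity threshold
#'
#' An interval counts as active swimming when its speed strictly exceeds the
#' threshold (default 4 cm/s, correcting for passive drift); a reading at
#' exactly the threshold is inactive. Undefined intervals stay `NA`.
#'
#' @param speeds a speed series from [compute_speed()].
#' @param threshold activity threshold, cm/s.
#' @return the speed series with an `active` logical column.
#' @export
classify_activity <- function(speeds, threshold = 4) {
  stopifnot(is.data.frame(speeds), "speed" %in% names(speeds))
  if (!is.numeric(threshold) || threshold < 0) {
    abort("threshold must be a non-negative speed (cm/s)")
  }
  speeds$active <- speeds$speed > threshold
  attr(speeds, "threshold") <- threshold
  speeds
}

#' Detect rest bouts
#'
#' A rest bout is a maximal run of consecutive inactive intervals whose total
#' duration strictly exceeds `min_duration` (default 60 s). Undefined
#' intervals (long tracking gaps) are neither active nor inactive and break
#' runs, so tracker dropout is never scored as rest.
#'
#' @param speeds a classified speed series (see [classify_activity()]).
#' @param min_duration minimum rest duration, s (strict inequality).
#' @return tibble of bouts: `start_s`, `duration_s`, time-ordered and
#'   non-overlapping.
#' @export
detect_rest_bouts <- function(speeds, min_duration = 60) {
  stopifnot(is.data.frame(speeds), "active" %in% names(speeds))
  n <- nrow(speeds)
  empty <- tibble(start_s = numeric(0), duration_s = numeric(0))
  if (n == 0) return(empty)
  # encode NA as its own run value so gaps split rest runs
  state <- ifelse(is.na(speeds$active), 2L, as.integer(speeds$active))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values == 0L
  if (!any(keep)) return(empty)
  istart <- starts[keep]
  iend <- ends[keep]
  start_s <- speeds$time_s[istart] - speeds$dt[istart] / 2
  duration_s <- map_dbl(seq_along(istart),
                        function(k) sum(speeds$dt[istart[k]:iend[k]]))
  out <- tibble(start_s = start_s, duration_s = duration_s)
  out[out$duration_s > min_duration, ]
}

#' Summarise activity, waking velocity and rest for one animal
#'
#' Totals over the recording: distance travelled while active (`cm`), mean
#' speed over active intervals (waking velocity, cm/s; `NA` when no interval
#' is active), and summed rest-bout duration (h).
#'
#' @param speeds classified speed series.
#' @param bouts rest bouts from [detect_rest_bouts()].
#' @return one-row tibble: `animal_id`, `species`, `lineage_group`,
#'   `total_activity_cm`, `waking_velocity_cms`, `total_rest_h`,
#'   `recording_h`, `n_bouts`, `frac_missing`.
#' @export
summarize_activity <- function(speeds, bouts) {
  stopifnot(is.data.frame(speeds), "active" %in% names(speeds))
  act <- !is.na(speeds$active) & speeds$active
  total_activity <- sum(speeds$speed[act] * speeds$dt[act])
  waking <- if (any(act)) mean(speeds$speed[act]) else NA_real_
  rest_h <- sum(bouts$duration_s) / 3600
  dur <- attr(speeds, "duration_s") %||% sum(speeds$dt)
  tibble(
    animal_id = attr(speeds, "animal_id") %||% NA_character_,
    species = attr(speeds, "species") %||% NA_character_,
    lineage_group = attr(speeds, "lineage_group") %||% NA_character_,
    total_activity_cm = total_activity,
    waking_velocity_cms = waking,
    total_rest_h = rest_h,
    recording_h = dur / 3600,
    n_bouts = nrow(bouts),
    frac_missing = mean(is.na(speeds$active))
  )
}

#' Score one animal end to end
#'
#' Convenience wrapper chaining [compute_speed()], [classify_activity()],
#' [detect_rest_bouts()] and [summarize_activity()].
#'
#' @param traj a `cf_trajectory`.
#' @param threshold activity threshold, cm/s.
#' @param min_rest minimum rest-bout duration, s.
#' @param max_gap maximum interpolated gap, s.
#' @return list with elements `speeds`, `bouts`, `summary`.
#' @export
score_animal <- function(traj, threshold = 4, min_rest = 60, max_gap = 2) {
  speeds <- classify_activity(compute_speed(traj, max_gap = max_gap),
                              threshold = threshold)
  bouts <- detect_rest_bouts(speeds, min_duration = min_rest)
  list(speeds = speeds, bouts = bouts,
       summary = summarize_activity(speeds, bouts))
}
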