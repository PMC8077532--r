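# Independent brute-force oracles, deliberately written as literal loops so
# they share no code path with the implementation they check.

# per-interval speeds by explicit per-frame displacement
oracle_speeds <- function(t, x, y) {
  out <- numeric(length(t) - 1)
  for (i in seq_along(out)) {
    out[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2) / (t[i + 1] - t[i])
  }
  out
}

# exhaustive run-scan for rest bouts over interval flags; active may contain
# NA (undefined interval, breaks runs); each interval has length dt seconds
# and interval i starts at (i-1)*dt
oracle_bouts <- function(active, dt, min_duration = 60) {
  starts <- c()
  durs <- c()
  run_start <- NA
  run_len <- 0
  flush <- function(run_start, run_len) {
    if (!is.na(run_start) && run_len * dt > min_duration) {
      starts <<- c(starts, (run_start - 1) * dt)
      durs <<- c(durs, run_len * dt)
    }
  }
  for (i in seq_along(active)) {
    inactive <- !is.na(active[i]) && !active[i]
    if (inactive) {
      if (is.na(run_start)) run_start <- i
      run_len <- run_len + 1
    } else {
      flush(run_start, run_len)
      run_start <- NA
      run_len <- 0
    }
  }
  flush(run_start, run_len)
  data.frame(start_s = starts %||% numeric(0),
             duration_s = durs %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a speed series tibble directly (bypassing position data) for
# boundary tests of classification and bout detection
make_speed_series <- function(speeds, frame_rate = 15, start_zt = 3,
                              active = NULL) {
  n <- length(speeds)
  dt <- 1 / frame_rate
  out <- tibble::tibble(time_s = (seq_len(n) - 0.5) * dt,
                        dt = rep(dt, n), speed = speeds)
  if (!is.null(active)) out$active <- active
  structure(out, class = c("cf_speed", class(out)),
            animal_id = "test", species = "test",
            frame_rate = frame_rate, start_zt = start_zt,
            duration_s = n * dt)
}

# write a small tracking CSV and return its path
write_tmp_tracking <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}
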