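test_that("read_tracking_table parses well-formed tables and applies calibration", {
  path <- write_tmp_tracking(data.frame(time = 0:2, x = c(0, 1, 2), y = c(0, 0, 1)))
  traj <- read_tracking_table(path, calibration = 1, animal_id = "a1",
                              frame_rate = 1)
  expect_s3_class(traj, "cf_trajectory")
  expect_equal(nrow(traj), 3)
  expect_equal(traj$x, c(0, 1, 2))

  traj2 <- read_tracking_table(path, calibration = 2.5, frame_rate = 1)
  expect_equal(traj2$x, c(0, 2.5, 5))
})

test_that("lost fixes become missing frames, never dropped", {
  path <- write_tmp_tracking(data.frame(time = 0:3, x = c(0, NA, 2, 3),
                                        y = c(0, NA, 0, 0)))
  traj <- read_tracking_table(path, frame_rate = 1)
  expect_equal(nrow(traj), 4)
  expect_equal(missing_frames(traj), 2L)
})

test_that("malformed rows and non-monotone time raise named errors", {
  bad <- write_tmp_tracking(data.frame(time = 0:2, x = c("0", "oops", "2"),
                                       y = c(0, 1, 2)))
  expect_error(read_tracking_table(bad, frame_rate = 1), "line 2")
  nonmono <- write_tmp_tracking(data.frame(time = c(0, 2, 1), x = 0:2, y = 0:2))
  expect_error(read_tracking_table(nonmono, frame_rate = 1), "monoton")
  expect_error(read_tracking_table(write_tmp_tracking(
    data.frame(time = 0:1, x = 0:1, y = 0:1)), calibration = 0), "calibration")
})

test_that("synthetic fixtures round-trip through write/read", {
  sim <- generate_trajectory(chronotype_spec(dropout_rate = 0.05),
                             duration_h = 0.1, frame_rate = 15, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_table(sim$trajectory, path)
  back <- read_tracking_table(path, animal_id = "rt", frame_rate = 15)
  expect_equal(back$x, sim$trajectory$x, tolerance = 1e-12)
  expect_equal(back$y, sim$trajectory$y, tolerance = 1e-12)
  expect_equal(missing_frames(back), missing_frames(sim$trajectory))
})

test_that("compute_speed matches analytic and brute-force displacement", {
  traj <- trajectory(data.frame(time_s = c(0, 1), x = c(0, 4), y = c(0, 0)),
                     animal_id = "a", frame_rate = 1)
  sp <- compute_speed(traj)
  expect_equal(sp$speed, 4)

  const <- trajectory(data.frame(time_s = 0:9, x = rep(2, 10), y = rep(3, 10)),
                      animal_id = "c", frame_rate = 1)
  expect_equal(compute_speed(const)$speed, rep(0, 9))

  set.seed(42)
  n <- 100
  walk <- trajectory(data.frame(time_s = (0:(n - 1)) / 15,
                                x = cumsum(rnorm(n)), y = cumsum(rnorm(n))),
                     animal_id = "w", frame_rate = 15)
  sp <- compute_speed(walk)
  expect_equal(sp$speed, oracle_speeds(walk$time_s, walk$x, walk$y),
               tolerance = 1e-12)
})

test_that("gap handling: short gaps interpolated, long gaps undefined", {
  # 1 missing frame at 1 fps = 1 s gap (<= 2 s): interpolated
  traj <- trajectory(data.frame(time_s = 0:4, x = c(0, 1, NA, 3, 4),
                                y = rep(0, 5)), animal_id = "g", frame_rate = 1)
  sp <- compute_speed(traj, max_gap = 2)
  expect_equal(sp$speed, rep(1, 4))
  # 3 missing frames = 3 s gap (> 2 s): intervals touching it undefined
  traj2 <- trajectory(data.frame(time_s = 0:6,
                                 x = c(0, 1, NA, NA, NA, 5, 6),
                                 y = rep(0, 7)), animal_id = "g2", frame_rate = 1)
  sp2 <- compute_speed(traj2, max_gap = 2)
  expect_equal(sum(is.na(sp2$speed)), 4)
  expect_equal(sp2$speed[c(1, 6)], c(1, 1))
  expect_error(compute_speed(trajectory(
    data.frame(time_s = 0:2, x = rep(NA_real_, 3), y = rep(NA_real_, 3)),
    animal_id = "allna", frame_rate = 1)), "missing")
})

test_that("activity classification uses a strict threshold", {
  sp <- make_speed_series(c(4.1, 4.0, 3.9, 8, 0, 8, 0))
  cl <- classify_activity(sp, threshold = 4)
  expect_equal(cl$active, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("rest bouts respect the strict >60 s rule at 15 fps", {
  fr <- 15
  # 61 s of inactivity inside a longer record -> exactly one 61 s bout
  n_rest <- 61 * fr
  flags <- c(rep(TRUE, 30), rep(FALSE, n_rest), rep(TRUE, 30))
  sp <- make_speed_series(ifelse(flags, 8, 0), frame_rate = fr, active = flags)
  bouts <- detect_rest_bouts(sp, min_duration = 60)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$duration_s, 61)
  expect_equal(bouts$start_s, 30 / fr)

  # exactly 60.0 s -> zero bouts; one more frame (60.0667 s) -> one bout
  for (extra in c(0, 1)) {
    flags <- c(rep(TRUE, 10), rep(FALSE, 900 + extra), rep(TRUE, 10))
    sp <- make_speed_series(ifelse(flags, 8, 0), frame_rate = fr, active = flags)
    expect_equal(nrow(detect_rest_bouts(sp, 60)), extra)
  }
})

test_that("undefined intervals break rest runs", {
  fr <- 1
  act <- c(rep(FALSE, 50), NA, rep(FALSE, 50))
  sp <- make_speed_series(rep(0, 101), frame_rate = fr, active = act)
  expect_equal(nrow(detect_rest_bouts(sp, 60)), 0)
  act2 <- c(rep(FALSE, 70), NA, rep(FALSE, 70))
  expect_equal(nrow(detect_rest_bouts(
    make_speed_series(rep(0, 141), frame_rate = fr, active = act2), 60)), 2)
})

test_that("bout detection equals the exhaustive run-scan on random inputs", {
  set.seed(99)
  fr <- 15
  for (rep_i in 1:5) {
    n <- 10000
    flags <- runif(n) < 0.3
    flags[sample(n, 50)] <- NA
    sp <- make_speed_series(ifelse(is.na(flags), NA, ifelse(flags, 8, 0)),
                            frame_rate = fr, active = flags)
    got <- detect_rest_bouts(sp, 60)
    want <- oracle_bouts(flags, 1 / fr, 60)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_s, want$start_s, tolerance = 1e-9)
    expect_equal(got$duration_s, want$duration_s, tolerance = 1e-9)
  }
})

test_that("summarize_activity handles the analytic cases", {
  fr <- 1
  # 2 h all below threshold: zero activity, one 2 h bout, no waking velocity
  n <- 2 * 3600
  sp <- classify_activity(make_speed_series(rep(1, n), frame_rate = fr))
  bouts <- detect_rest_bouts(sp)
  s <- summarize_activity(sp, bouts)
  expect_equal(s$total_activity_cm, 0)
  expect_true(is.na(s$waking_velocity_cms))
  expect_equal(nrow(bouts), 1)
  expect_equal(s$total_rest_h, 2)

  # constant 8 cm/s for 1 h: waking velocity 8, distance 28800 cm
  n <- 3600
  sp <- classify_activity(make_speed_series(rep(8, n), frame_rate = fr))
  s <- summarize_activity(sp, detect_rest_bouts(sp))
  expect_equal(s$waking_velocity_cms, 8)
  expect_equal(s$total_activity_cm, 28800)
})

test_that("raising the threshold never decreases rest nor increases activity", {
  sim <- generate_trajectory(chronotype_spec(rest_fraction = 0.3),
                             duration_h = 0.5, frame_rate = 15, seed = 5)
  sp <- compute_speed(sim$trajectory)
  prev_rest <- -Inf
  prev_act <- Inf
  for (thr in c(1, 2, 4, 6, 10)) {
    cl <- classify_activity(sp, thr)
    s <- summarize_activity(cl, detect_rest_bouts(cl))
    expect_gte(s$total_rest_h, prev_rest)
    expect_lte(s$total_activity_cm, prev_act)
    prev_rest <- s$total_rest_h
    prev_act <- s$total_activity_cm
  }
})

test_that("rest + active + short-subthreshold time conserves the recording", {
  sim <- generate_trajectory(chronotype_spec(rest_fraction = 0.5),
                             duration_h = 1, frame_rate = 15, seed = 21)
  sc <- score_animal(sim$trajectory)
  sp <- sc$speeds
  active_h <- sum(sp$dt[!is.na(sp$active) & sp$active]) / 3600
  short_inactive_h <- sum(sp$dt[!is.na(sp$active) & !sp$active]) / 3600 -
    sc$summary$total_rest_h
  expect_equal(sc$summary$total_rest_h + active_h + short_inactive_h,
               sc$summary$recording_h, tolerance = 1 / 15 / 3600 * 2)
})
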