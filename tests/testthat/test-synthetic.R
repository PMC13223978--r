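test_that("generators are deterministic under a fixed seed", {
  sc <- activity_scenario(epoch_schedule(total_s = 20))
  a1 <- generate_activity_session(sc, seed = 9)
  a2 <- generate_activity_session(sc, seed = 9)
  expect_identical(a1$session$thoracic$channels$z$samples,
                   a2$session$thoracic$channels$z$samples)
  a3 <- generate_activity_session(sc, seed = 10)
  expect_false(identical(a1$session$thoracic$channels$z$samples,
                         a3$session$thoracic$channels$z$samples))

  gsc <- gait_scenario(duration_s = 12,
                       bouts = tibble::tibble(start_s = 2, duration_s = 8))
  g1 <- generate_gait_session(gsc, seed = 4)
  g2 <- generate_gait_session(gsc, seed = 4)
  expect_identical(g1$session$hip_left$samples, g2$session$hip_left$samples)
})

test_that("generated yaw magnitudes respect the declared bins before noise", {
  sc <- activity_scenario(epoch_schedule(total_s = 30), noise_sd = 0)
  a <- generate_activity_session(sc, seed = 2)
  yaw <- abs(a$session$lumbar$channels$z$samples)
  tt <- (seq_along(yaw) - 1) / sc$rate
  thr <- activity_thresholds()
  for (i in seq_len(nrow(a$truth))) {
    idx <- tt >= a$truth$start_s[i] & tt < a$truth$end_s[i]
    rng <- range(yaw[idx])
    if (a$truth$state[i] == "rest") expect_lt(rng[2], thr$rest_upper)
    if (a$truth$state[i] == "low") {
      expect_gte(rng[1], thr$rest_upper); expect_lt(rng[2], thr$low_upper)
    }
    if (a$truth$state[i] == "high") expect_gte(rng[1], thr$low_upper)
  }
})

test_that("the hip template passes exactly through the prescribed extrema", {
  for (pars in list(c(25, -15, 40, 85), c(18, -5, 30, 70), c(30, -22, 55, 10))) {
    ang <- hip_template(seq(0, 100, by = 0.01), pars[1], pars[2],
                        pars[3], pars[4])
    expect_equal(max(ang), pars[1], tolerance = 1e-6)
    expect_equal(min(ang), pars[2], tolerance = 1e-6)
    grid <- seq(0, 100, by = 0.01)
    expect_equal(grid[which.max(ang)], pars[3], tolerance = 0.02)
    expect_equal(grid[which.min(ang)], pars[4], tolerance = 0.02)
  }
})

test_that("in-band stride bouts are detected; out-of-band strides are not", {
  cfg <- gait_config()
  sc <- gait_scenario()   # 3 Hz steps, three 10-s bouts in 60 s
  g <- generate_gait_session(sc, seed = 5)
  ml <- butterworth_lowpass(resample_signal(
    g$session$thoracic$channels$y, 1000))
  blocks <- walking_blocks(ml, cfg)
  truth <- bout_block_labels(g$truth$bouts, sc$duration_s, cfg)
  expect_gte(mean(blocks$walking == truth$walking_true), 0.95)

  out_band <- gait_scenario(stride_hz = 1.5)
  g2 <- generate_gait_session(out_band, seed = 5)
  ml2 <- butterworth_lowpass(resample_signal(
    g2$session$thoracic$channels$y, 1000))
  expect_equal(nrow(detect_walking(ml2, cfg)), 0L)
})

test_that("truth cycles carry both timing frames and match the template", {
  sc <- gait_scenario(duration_s = 20,
                      bouts = tibble::tibble(start_s = 3, duration_s = 12))
  g <- generate_gait_session(sc, seed = 8)
  tc <- g$truth$cycles
  expect_gt(nrow(tc), 3)
  expect_equal(unique(tc$rom), sc$peak_flexion - sc$peak_extension)
  expect_equal(unique(tc$pct_at_min_peakframe),
               (sc$pct_at_min - sc$pct_at_max) %% 100)
  expect_equal(diff(tc$onset_s[tc$bout == 1]),
               rep(sc$cycle_s, sum(tc$bout == 1) - 1), tolerance = 1e-9)
})

test_that("bouts overlapping the recording end are truncated with a warning", {
  expect_warning(
    sc <- gait_scenario(duration_s = 10,
                        bouts = tibble::tibble(start_s = 6, duration_s = 10)),
    class = "pigait_warning_truncated")
  expect_equal(sc$bouts$duration_s, 4)
})

test_that("a full study writes a complete, reproducible manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  des <- study_design(activity_minutes = 0.1, gait_seconds = 12)
  m1 <- generate_study(des, d1, seed = 3)
  m2 <- generate_study(des, d2, seed = 3)
  expect_equal(length(m1$sessions), 12L)  # 4 animals x 3 sessions
  expect_identical(jsonlite::toJSON(m1$sessions), jsonlite::toJSON(m2$sessions))
  # session files identical byte-for-byte across regenerations
  f1 <- file.path(d1, "P1_Baseline_gait_goniometer.csv")
  f2 <- file.path(d2, "P1_Baseline_gait_goniometer.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(file.exists(file.path(d1, "ptibs.csv")))
})
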