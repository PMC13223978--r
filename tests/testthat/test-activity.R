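test_that("dorsal-plane magnitude selects the yaw axis and rectifies it", {
  expect_equal(dorsal_plane_magnitude(constant_triad(7))$samples,
               rep(7, 4000), tolerance = 1e-9)
  expect_equal(dorsal_plane_magnitude(constant_triad(-7))$samples,
               rep(7, 4000), tolerance = 1e-9)
  # pure roll motion: yaw stays zero
  roll <- imu_triad(
    x = sine_channel(2, 2000, 2, amplitude = 30),
    y = signal_channel(rep(0, 4001), 2000),
    z = signal_channel(rep(0, 4001), 2000),
    placement = "lumbar_L3")
  expect_equal(max(dorsal_plane_magnitude(roll)$samples), 0, tolerance = 1e-12)
  # a triad without a yaw assignment is a configuration error
  noyaw <- constant_triad(7)
  noyaw$axis_map$yaw <- NULL
  expect_error(dorsal_plane_magnitude(noyaw), class = "pigait_error_config")
})

test_that("intensity binning follows the half-open 5/50 partition", {
  thr <- activity_thresholds()
  lab <- classify_intensity(c(0, 4.999, 5, 30, 49.999, 50, 60), thr)
  expect_equal(as.character(lab),
               c("Rest", "Rest", "Low", "Low", "Low", "High", "High"))
  expect_error(classify_intensity(c(1, -0.1), thr),
               class = "pigait_error_internal")
  expect_error(activity_thresholds(50, 5), class = "pigait_error_parameter")
})

test_that("fractions sum to 100 and non-rest counts Low+High", {
  lab <- classify_intensity(c(0, 0, 10, 60), activity_thresholds())
  fr <- intensity_fractions(lab)
  expect_equal(fr$fraction_rest + fr$fraction_low + fr$fraction_high, 100,
               tolerance = 1e-9)
  expect_equal(fr$non_rest_pct, 50)
  expect_equal(non_rest_percentage(classify_intensity(rep(1, 10),
                                                      activity_thresholds())), 0)
  expect_equal(non_rest_percentage(classify_intensity(c(1, 1, 10, 10),
                                                      activity_thresholds())), 50)
  expect_equal(non_rest_percentage(classify_intensity(c(1, 10, 60, 60),
                                                      activity_thresholds())), 75)
  expect_error(intensity_fractions(factor(character(),
                                          c("Rest", "Low", "High"))),
               class = "pigait_error_parameter")
})

test_that("recovery is the session value as a percent of the Baseline mean", {
  expect_equal(recovery_percentage(50, c(50)), 100)
  expect_equal(recovery_percentage(20, c(40, 60)), 40)
  expect_equal(recovery_percentage(55, 50), 110)
  expect_warning(out <- recovery_percentage(10, 0),
                 class = "pigait_warning_baseline")
  expect_true(is.na(out))
})

test_that("raising the rest threshold never increases non-rest percentage", {
  set.seed(5)
  mags <- abs(rnorm(2000, 20, 25))
  prev <- Inf
  for (ru in c(2, 5, 10, 20, 40)) {
    nr <- non_rest_percentage(
      classify_intensity(mags, activity_thresholds(rest_upper = ru)))
    expect_lte(nr, prev)
    prev <- nr
  }
})

test_that("scheduled rest/low/high fractions are recovered from short sessions", {
  sc <- activity_scenario(epoch_schedule(total_s = 60,
                                         fractions = c(rest = 0.6, low = 0.3,
                                                       high = 0.1)))
  a <- generate_activity_session(sc, seed = 21)
  summ <- summarize_activity(a$session)
  truth <- attr(a$truth, "fractions")
  for (i in seq_len(nrow(summ))) {
    expect_lt(abs(summ$fraction_rest[i] - truth[["rest"]]), 2)
    expect_lt(abs(summ$fraction_low[i] - truth[["low"]]), 2)
    expect_lt(abs(summ$fraction_high[i] - truth[["high"]]), 2)
  }
})

test_that("an all-zero session is 100% rest and zero animals vary gives SEM 0", {
  zch <- function() signal_channel(rep(0, 2000), 1000)
  zt <- function(p) imu_triad(zch(), zch(), zch(), p)
  ses <- session_recording("A1", "DAMAGED", "Baseline",
                           thoracic = zt("thoracic_T4"),
                           lumbar = zt("lumbar_L3"))
  summ <- summarize_activity(ses)
  expect_equal(summ$fraction_rest, c(100, 100))
  expect_equal(summ$non_rest_pct, c(0, 0))
  # two identical animals: group SEM 0
  two <- dplyr::bind_rows(
    dplyr::mutate(summ, animal = "A1"),
    dplyr::mutate(summ, animal = "A2"))
  grp <- activity_group_summary(two)
  expect_equal(grp$non_rest_pct_sem, rep(0, nrow(grp)))
  expect_equal(grp$n, rep(2L, nrow(grp)))
})
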