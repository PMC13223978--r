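test_that("block-wise FFT flags in-band dominant frequencies as walking", {
  ch <- sine_channel(3, 1000, 20)
  blocks <- walking_blocks(ch)
  expect_equal(nrow(blocks), 4L)
  expect_true(all(blocks$walking))
  expect_true(all(abs(blocks$dominant_frequency - 3) <= 0.2))
  iv <- detect_walking(ch)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$n_blocks, 4L)

  slow <- sine_channel(1, 1000, 20)
  expect_equal(nrow(detect_walking(slow)), 0L)

  short <- sine_channel(3, 1000, 2)
  expect_warning(out <- walking_blocks(short), class = "pigait_warning_short")
  expect_equal(nrow(out), 0L)
})

test_that("eligibility needs PTIBS above 3 and at least three cycles", {
  expect_false(gait_eligibility(1, 0))
  expect_true(gait_eligibility(8, 12))
  expect_false(gait_eligibility(4, 2))
  expect_true(gait_eligibility(3.5, 3))
  expect_false(gait_eligibility(3, 10))
})

test_that("cycles are delimited peak-flexion to peak-flexion", {
  ch <- sine_channel(1, 1000, 10, amplitude = 20, units = "deg")
  cyc <- segment_cycles(ch)
  expect_equal(nrow(cyc), 9L)
  expect_equal(cyc$duration_s, rep(1, 9), tolerance = 1e-3)
  flat <- signal_channel(rep(0, 5000), 1000, units = "deg")
  expect_equal(nrow(segment_cycles(flat)), 0L)
  # low-prominence ripples are not cycle boundaries
  ripple <- sine_channel(1, 1000, 10, amplitude = 2, units = "deg")
  expect_equal(nrow(segment_cycles(ripple)), 0L)
})

test_that("cycle retention honours duration bounds and the per-session cap", {
  ch <- sine_channel(1, 1000, 30, amplitude = 20, units = "deg")
  cyc <- segment_cycles(ch)   # 29 available, cap 10
  expect_equal(nrow(cyc), 10L)
  fast <- sine_channel(4, 1000, 10, amplitude = 20, units = "deg")
  expect_equal(nrow(segment_cycles(fast)), 0L)  # 0.25 s cycles out of bounds
})

test_that("time normalization maps any cycle onto 101 points exactly", {
  ramp <- normalize_cycle(seq(0, 10, length.out = 51))
  expect_equal(nrow(ramp), 101L)
  expect_equal(ramp$angle, 0.1 * (0:100), tolerance = 1e-9)
  # 201 input samples coincide with the output grid every other sample
  x <- rnorm(201)
  nc <- normalize_cycle(x)
  expect_equal(nc$angle, x[seq(1, 201, by = 2)], tolerance = 1e-9)
  expect_error(normalize_cycle(c(1, 2, 3)), class = "pigait_error_parameter")
  # endpoints always equal the raw cycle's endpoints
  y <- cumsum(rnorm(37))
  nc2 <- normalize_cycle(y)
  expect_equal(nc2$angle[c(1, 101)], y[c(1, 37)])
  # dense sinusoid: interpolated max within 0.5% of the analytic amplitude
  s <- 12 * sin(2 * pi * seq(0, 1, length.out = 1000))
  expect_lt(abs(max(normalize_cycle(s)$angle) - 12) / 12, 0.005)
})

test_that("cycle metrics locate extrema and first-occurrence ties", {
  s <- 10 * sin(2 * pi * (0:100) / 100)
  m <- cycle_metrics(normalize_cycle_ok <- tibble::tibble(pct = 0:100, angle = s))
  expect_equal(m$max_angle, 10, tolerance = 1e-9)
  expect_equal(m$min_angle, -10, tolerance = 1e-9)
  expect_equal(m$rom, 20, tolerance = 1e-9)
  expect_equal(m$pct_at_max, 25)
  expect_equal(m$pct_at_min, 75)
  mc <- cycle_metrics(rep(5, 101))
  expect_equal(mc$max_angle, 5)
  expect_equal(mc$rom, 0)
  expect_equal(mc$pct_at_max, 0)
  expect_equal(mc$pct_at_min, 0)
})

test_that("normalization keeps global extrema within the curvature bound", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(40:400, 1)
    amp <- runif(1, 5, 30)
    ph <- runif(1, 0, 2 * pi)
    x <- amp * sin(2 * pi * seq(0, 1, length.out = n) + ph)
    # |f''| <= amp*(2*pi)^2 on the unit cycle; the interpolant can miss the
    # continuous max by the input-grid (step 1/(n-1)) interpolation error
    # plus the output-grid (step 1/100) sampling error
    bound <- amp * (2 * pi)^2 / 8 * (1 / (n - 1)^2 + 1 / 100^2)
    m <- cycle_metrics(normalize_cycle(x))
    expect_lte(max(x) - m$max_angle, bound + 1e-12)
    expect_gte(m$rom, 0)
  }
})

test_that("representative cycle averages curves and metrics separately", {
  base <- normalize_cycle(10 * sin(2 * pi * seq(0, 1, length.out = 101)))
  rep10 <- representative_cycle(rep(list(base), 10))
  expect_equal(rep10$curve$mean_angle, base$angle)
  expect_equal(rep10$curve$sem_angle, rep(0, 101))
  expect_equal(rep10$n_cycles, 10L)

  two <- representative_cycle(list(tibble::tibble(pct = 0:100, angle = rep(0, 101)),
                                   tibble::tibble(pct = 0:100, angle = rep(10, 101))))
  expect_equal(two$curve$mean_angle, rep(5, 101))

  # asynchronous peaks: averaged per-cycle metrics exceed the mean curve's max
  c1 <- normalize_cycle(10 * sin(2 * pi * seq(0, 1, length.out = 101)))
  c2 <- normalize_cycle(10 * cos(2 * pi * seq(0, 1, length.out = 101)))
  rc <- representative_cycle(list(c1, c2))
  expect_equal(rc$metrics$max_angle, 10, tolerance = 1e-6)
  expect_lt(max(rc$curve$mean_angle), 10)
  expect_error(representative_cycle(list()), class = "pigait_error_parameter")
})

test_that("baseline-relative deltas use signed denominators and point shifts", {
  base <- cycle_metrics(normalize_cycle(hip_template(0:100)))
  expect_equal(unlist(gait_delta(base, base)), rep(0, 5),
               ignore_attr = TRUE)
  b <- tibble::tibble(max_angle = 25, min_angle = -15, rom = 40,
                      pct_at_max = 40, pct_at_min = 85)
  p <- tibble::tibble(max_angle = 25, min_angle = -9.585, rom = 32,
                      pct_at_max = 30, pct_at_min = 85)
  d <- gait_delta(p, b)
  expect_equal(d$d_rom_pct, -20)
  expect_equal(d$d_min_pct, -36.1)
  expect_equal(d$d_pct_at_max, -10)
  z <- tibble::tibble(max_angle = 1, min_angle = -1, rom = 0,
                      pct_at_max = 10, pct_at_min = 60)
  expect_warning(dz <- gait_delta(b, z), class = "pigait_warning_baseline")
  expect_true(is.na(dz$d_rom_pct))
})
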