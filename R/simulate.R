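#' Build a deterministic epoch schedule
#'
#' Interleaves rest/low/high epochs so that the scheduled time fractions are
#' met exactly, emulating the alternating recumbency and activity bouts of an
#' unsupervised pen recording.
#'
#' @param total_s Total duration in seconds (default 1800 = 30 min).
#' @param fractions Named fractions for `rest`, `low`, `high` summing to 1.
#' @param epoch_s Nominal epoch length in seconds (default 30).
#' @return A tibble: `duration_s`, `state`.
#' @export
epoch_schedule <- function(total_s = 1800,
                           fractions = c(rest = 0.6, low = 0.3, high = 0.1),
                           epoch_s = 30) {
  stopifnot(all(c("rest", "low", "high") %in% names(fractions)),
            abs(sum(fractions) - 1) < 1e-9, total_s > 0, epoch_s > 0)
  n_rep <- max(1L, floor(total_s / (epoch_s / max(fractions))))
  # one repeating pattern block carrying the exact fractions
  block <- tibble::tibble(
    state = c("rest", "low", "rest", "high"),
    weight = c(fractions[["rest"]] / 2, fractions[["low"]],
               fractions[["rest"]] / 2, fractions[["high"]])
  )
  block <- block[block$weight > 0, , drop = FALSE]
  block_s <- max(epoch_s / max(block$weight), 1)
  n_blocks <- max(1L, round(total_s / block_s))
  sched <- block[rep(seq_len(nrow(block)), n_blocks), ]
  sched$duration_s <- sched$weight * (total_s / n_blocks)
  tibble::tibble(duration_s = sched$duration_s, state = sched$state)
}

#' Activity-session scenario
#'
#' Describes a synthetic unsupervised activity recording: an epoch schedule
#' of rest/low/high states, per-state magnitude ranges drawn uniformly
#' *inside* the corresponding intensity bin (with a margin so additive sensor
#' noise does not leak across bin edges), and Gaussian sensor noise.
#'
#' @param epochs Tibble (`duration_s`, `state`) from [epoch_schedule()].
#' @param rate IMU sampling rate in Hz (default 2000).
#' @param noise_sd Additive Gaussian sensor noise SD in deg/s^2 (default 0.5).
#' @param ranges Named list of in-bin magnitude ranges per state.
#' @return A list of class `activity_scenario`.
#' @export
activity_scenario <- function(epochs = epoch_schedule(), rate = 2000,
                              noise_sd = 0.5,
                              ranges = list(rest = c(0.5, 4),
                                            low = c(7, 45),
                                            high = c(55, 150))) {
  if (nrow(epochs) == 0L) {
    abort("Epoch schedule is empty.", class = "pigait_error_parameter")
  }
  stopifnot(all(epochs$duration_s > 0),
            all(epochs$state %in% c("rest", "low", "high")))
  structure(list(epochs = epochs, rate = rate, noise_sd = noise_sd,
                 ranges = ranges),
            class = "activity_scenario")
}

# slowly varying in-range magnitude: uniform knots at 2 Hz, linear interp
slow_uniform <- function(n, rate, range, knot_hz = 2) {
  n_knots <- max(2L, ceiling(n / rate * knot_hz) + 1L)
  knots <- stats::runif(n_knots, range[1], range[2])
  approx(seq(0, 1, length.out = n_knots), knots,
         xout = seq(0, 1, length.out = n), rule = 2)$y
}

#' Generate a synthetic activity session with ground truth
#'
#' Deterministic for a fixed seed. The yaw-axis channels of both triads carry
#' slowly varying magnitudes drawn inside the scheduled state's bin (constant
#' sign per epoch, so smoothing does not cancel the signal), plus Gaussian
#' noise; off-role axes carry noise only.
#'
#' @param scenario An [activity_scenario()].
#' @param animal_id,group,session Metadata for the resulting recording.
#' @param seed Integer seed (required; the generator is seeded explicitly).
#' @return A list: `session` (a [session_recording()] without goniometers)
#'   and `truth` (tibble `start_s`, `end_s`, `state`, plus scheduled
#'   fractions as attribute `fractions`).
#' @export
generate_activity_session <- function(scenario, animal_id = "SIM",
                                      group = "DAMAGED",
                                      session = "Baseline", seed) {
  stopifnot(inherits(scenario, "activity_scenario"))
  if (missing(seed)) abort("An explicit `seed` is required.",
                           class = "pigait_error_parameter")
  set.seed(seed)
  rate <- scenario$rate
  ep <- scenario$epochs
  n_per <- pmax(1L, round(ep$duration_s * rate))
  n <- sum(n_per)
  make_yaw <- function() {
    pieces <- purrr::map(seq_len(nrow(ep)), function(i) {
      sgn <- sample(c(-1, 1), 1L)
      sgn * slow_uniform(n_per[i], rate, scenario$ranges[[ep$state[i]]])
    })
    unlist(pieces) + stats::rnorm(n, 0, scenario$noise_sd)
  }
  make_triad <- function(placement) {
    noise_ch <- function(axis) {
      signal_channel(stats::rnorm(n, 0, scenario$noise_sd), rate,
                     units = "deg/s^2", axis = axis)
    }
    imu_triad(
      x = noise_ch("cranio-caudal rotational"),
      y = noise_ch("medio-lateral"),
      z = signal_channel(make_yaw(), rate, units = "deg/s^2",
                         axis = "dorsal-plane-rotational"),
      placement = placement
    )
  }
  ends <- cumsum(n_per) / rate
  truth <- tibble::tibble(start_s = c(0, head(ends, -1L)), end_s = ends,
                          state = ep$state)
  fr <- tapply(ep$duration_s, factor(ep$state, c("rest", "low", "high")), sum)
  fr[is.na(fr)] <- 0
  attr(truth, "fractions") <- 100 * fr / sum(ep$duration_s)
  list(
    session = session_recording(animal_id, group, session,
                                thoracic = make_triad("thoracic_T4"),
                                lumbar = make_triad("lumbar_L3")),
    truth = truth
  )
}

#' Periodic hip-angle template
#'
#' Piecewise-cosine waveform anchored exactly at the prescribed extrema:
#' peak flexion `peak_flexion` at `pct_at_max` percent of the cycle and peak
#' extension `peak_extension` at `pct_at_min`, joined by half-cosine arcs
#' (continuously differentiable, zero slope at both extrema). Using anchored
#' cosine arcs rather than a spline through the two extrema guarantees the
#' realized extrema equal the prescribed ones, which is what makes the
#' generator usable as a recovery oracle.
#'
#' @param phase_pct Phase in percent of cycle (any real; wrapped mod 100).
#' @param peak_flexion Peak flexion angle in degrees (> 0).
#' @param peak_extension Peak extension angle in degrees (< 0).
#' @param pct_at_max,pct_at_min Cycle percentages of the extrema.
#' @return Angles in degrees.
#' @export
hip_template <- function(phase_pct, peak_flexion = 25, peak_extension = -15,
                         pct_at_max = 40, pct_at_min = 85) {
  stopifnot(peak_flexion > 0, peak_extension < 0,
            pct_at_max != pct_at_min,
            pct_at_max >= 0, pct_at_max <= 100,
            pct_at_min >= 0, pct_at_min <= 100)
  s1 <- (pct_at_min - pct_at_max) %% 100
  s2 <- 100 - s1
  u <- (phase_pct - pct_at_max) %% 100
  amp <- peak_flexion - peak_extension
  ifelse(u <= s1,
         peak_extension + amp * (1 + cos(pi * u / s1)) / 2,
         peak_extension + amp * (1 - cos(pi * (u - s1) / s2)) / 2)
}

#' Gait-session scenario
#'
#' Describes a synthetic corridor-walking recording: walking bouts during
#' which the thoracic medio-lateral channel oscillates at the step frequency
#' and the hip channels follow the periodic [hip_template()], with Gaussian
#' noise everywhere and cosine tapers at bout edges.
#'
#' @param duration_s Recording duration in seconds (default 60).
#' @param bouts Tibble (`start_s`, `duration_s`) of walking bouts.
#' @param stride_hz Thoracic oscillation (step) frequency in Hz (default 3,
#'   inside the 2.5-4.0 Hz walking band).
#' @param cycle_s Hip gait-cycle duration in seconds (default 0.6).
#' @param peak_flexion,peak_extension,pct_at_max,pct_at_min Hip waveform
#'   parameters, see [hip_template()]. `hip_active = FALSE` flattens the hip
#'   channels (no hindlimb cycles, as after a complete lesion).
#' @param hip_active Logical; hindlimb stepping present (default TRUE).
#' @param imu_amplitude Thoracic medio-lateral oscillation amplitude in
#'   deg/s^2 (default 30).
#' @param sway_hz,sway_amplitude Slow postural-sway component present
#'   throughout the recording (defaults 0.8 Hz, 8 deg/s^2): a standing or
#'   resting animal oscillates slowly rather than being spectrally silent,
#'   so non-walking blocks have an out-of-band dominant frequency.
#' @param imu_noise_sd IMU additive noise SD (default 3; signal RMS over
#'   noise SD then ~7).
#' @param hip_noise_sd Goniometer additive noise SD in degrees (default 0.5).
#' @param imu_rate,gonio_rate Sampling rates in Hz (defaults 2000 and 1000,
#'   exercising the resampling path).
#' @param taper_s Cosine taper length at bout edges in seconds (default 0.3).
#' @return A list of class `gait_scenario`.
#' @export
gait_scenario <- function(duration_s = 60,
                          bouts = tibble::tibble(start_s = c(5, 25, 45),
                                                 duration_s = c(10, 10, 10)),
                          stride_hz = 3, cycle_s = 0.6,
                          peak_flexion = 25, peak_extension = -15,
                          pct_at_max = 40, pct_at_min = 85,
                          hip_active = TRUE,
                          imu_amplitude = 30, sway_hz = 0.8,
                          sway_amplitude = 8, imu_noise_sd = 3,
                          hip_noise_sd = 0.5,
                          imu_rate = 2000, gonio_rate = 1000,
                          taper_s = 0.3) {
  stopifnot(nrow(bouts) >= 1L, all(bouts$duration_s > 0), duration_s > 0)
  if (hip_active) {
    stopifnot(peak_flexion > 0, peak_extension < 0, pct_at_max != pct_at_min)
  }
  over <- bouts$start_s + bouts$duration_s > duration_s
  if (any(over)) {
    warn("Bout(s) overlapping the recording end were truncated.",
         class = "pigait_warning_truncated")
    bouts$duration_s[over] <- pmax(0, duration_s - bouts$start_s[over])
    bouts <- bouts[bouts$duration_s > 0, , drop = FALSE]
  }
  structure(list(duration_s = duration_s, bouts = bouts,
                 stride_hz = stride_hz, cycle_s = cycle_s,
                 peak_flexion = peak_flexion, peak_extension = peak_extension,
                 pct_at_max = pct_at_max, pct_at_min = pct_at_min,
                 hip_active = hip_active,
                 imu_amplitude = imu_amplitude, sway_hz = sway_hz,
                 sway_amplitude = sway_amplitude, imu_noise_sd = imu_noise_sd,
                 hip_noise_sd = hip_noise_sd,
                 imu_rate = imu_rate, gonio_rate = gonio_rate,
                 taper_s = taper_s),
            class = "gait_scenario")
}

# cosine-taper envelope: 0 outside bouts, 1 in bout interiors
bout_envelope <- function(tt, bouts, taper_s) {
  env <- numeric(length(tt))
  for (k in seq_len(nrow(bouts))) {
    a <- bouts$start_s[k]; b <- a + bouts$duration_s[k]
    inb <- tt >= a & tt <= b
    u <- pmin(1, pmin(tt[inb] - a, b - tt[inb]) / taper_s)
    env[inb] <- pmax(env[inb], (1 - cos(pi * u)) / 2)
  }
  env
}

#' Generate a synthetic gait session with ground-truth cycle table
#'
#' Deterministic for a fixed seed. The truth table lists every hindlimb gait
#' cycle fully inside a bout's untapered interior: its flexion-peak onset
#' time and the template metrics in two frames -- the template frame
#' (`pct_at_max`, `pct_at_min` as prescribed) and the peak-delimited frame
#' the analysis observes, where a cycle starts at peak flexion
#' (`pct_at_max_peakframe` = 0, `pct_at_min_peakframe` =
#' `(pct_at_min - pct_at_max) mod 100`).
#'
#' @param scenario A [gait_scenario()].
#' @param animal_id,group,session Metadata.
#' @param seed Integer seed (required).
#' @return A list: `session` (a full [session_recording()]) and `truth`
#'   (list with `bouts` and per-cycle tibble `cycles`).
#' @export
generate_gait_session <- function(scenario, animal_id = "SIM",
                                  group = "DAMAGED", session = "Baseline",
                                  seed) {
  stopifnot(inherits(scenario, "gait_scenario"))
  if (missing(seed)) abort("An explicit `seed` is required.",
                           class = "pigait_error_parameter")
  set.seed(seed)
  sc <- scenario
  n_imu <- round(sc$duration_s * sc$imu_rate)
  n_gon <- round(sc$duration_s * sc$gonio_rate)
  t_imu <- (seq_len(n_imu) - 1L) / sc$imu_rate
  t_gon <- (seq_len(n_gon) - 1L) / sc$gonio_rate
  env_imu <- bout_envelope(t_imu, sc$bouts, sc$taper_s)
  env_gon <- bout_envelope(t_gon, sc$bouts, sc$taper_s)

  phase_of <- function(tt) {
    ph <- numeric(length(tt))
    for (k in seq_len(nrow(sc$bouts))) {
      a <- sc$bouts$start_s[k]; b <- a + sc$bouts$duration_s[k]
      inb <- tt >= a & tt <= b
      ph[inb] <- ((tt[inb] - a) / sc$cycle_s * 100) %% 100
    }
    ph
  }

  ml <- numeric(n_imu)
  for (k in seq_len(nrow(sc$bouts))) {
    a <- sc$bouts$start_s[k]; b <- a + sc$bouts$duration_s[k]
    inb <- t_imu >= a & t_imu <= b
    ml[inb] <- sc$imu_amplitude * sin(2 * pi * sc$stride_hz * (t_imu[inb] - a))
  }
  sway_phase <- stats::runif(1, 0, 2 * pi)
  ml <- ml * env_imu +
    sc$sway_amplitude * sin(2 * pi * sc$sway_hz * t_imu + sway_phase) +
    stats::rnorm(n_imu, 0, sc$imu_noise_sd)

  hip_of <- function(shift_pct) {
    if (!sc$hip_active) return(stats::rnorm(n_gon, 0, sc$hip_noise_sd))
    ang <- hip_template(phase_of(t_gon) + shift_pct, sc$peak_flexion,
                        sc$peak_extension, sc$pct_at_max, sc$pct_at_min)
    ang * env_gon + stats::rnorm(n_gon, 0, sc$hip_noise_sd)
  }

  imu_noise <- function(axis, n, rate) {
    signal_channel(stats::rnorm(n, 0, sc$imu_noise_sd), rate,
                   units = "deg/s^2", axis = axis)
  }
  thoracic <- imu_triad(
    x = imu_noise("cranio-caudal rotational", n_imu, sc$imu_rate),
    y = signal_channel(ml, sc$imu_rate, units = "deg/s^2",
                       axis = "medio-lateral"),
    z = imu_noise("dorsal-plane-rotational", n_imu, sc$imu_rate),
    placement = "thoracic_T4"
  )
  lumbar <- imu_triad(
    x = imu_noise("cranio-caudal rotational", n_imu, sc$imu_rate),
    y = imu_noise("medio-lateral", n_imu, sc$imu_rate),
    z = imu_noise("dorsal-plane-rotational", n_imu, sc$imu_rate),
    placement = "lumbar_L3"
  )
  hipL <- signal_channel(hip_of(0), sc$gonio_rate, units = "deg",
                         axis = "hip flexion/extension (left)")
  hipR <- signal_channel(hip_of(50), sc$gonio_rate, units = "deg",
                         axis = "hip flexion/extension (right)")

  cycles <- truth_cycles(sc)
  list(
    session = session_recording(animal_id, group, session,
                                thoracic = thoracic, lumbar = lumbar,
                                hip_left = hipL, hip_right = hipR),
    truth = list(bouts = sc$bouts, cycles = cycles)
  )
}

# every full hindlimb cycle (flexion peak to flexion peak) inside a bout's
# untapered interior, with metrics in both frames
truth_cycles <- function(sc) {
  empty <- tibble::tibble(bout = integer(), onset_s = numeric(),
                          duration_s = numeric(), max_angle = numeric(),
                          min_angle = numeric(), rom = numeric(),
                          pct_at_max = numeric(), pct_at_min = numeric(),
                          pct_at_min_peakframe = numeric())
  if (!sc$hip_active) return(empty)
  rows <- list()
  for (k in seq_len(nrow(sc$bouts))) {
    a <- sc$bouts$start_s[k]
    b <- a + sc$bouts$duration_s[k]
    lo <- a + sc$taper_s
    hi <- b - sc$taper_s
    first_peak <- a + (sc$pct_at_max / 100) * sc$cycle_s
    onsets <- seq(first_peak, b, by = sc$cycle_s)
    keep <- onsets >= lo & (onsets + sc$cycle_s) <= hi
    for (o in onsets[keep]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bout = k, onset_s = o, duration_s = sc$cycle_s,
        max_angle = sc$peak_flexion, min_angle = sc$peak_extension,
        rom = sc$peak_flexion - sc$peak_extension,
        pct_at_max = sc$pct_at_max, pct_at_min = sc$pct_at_min,
        pct_at_min_peakframe = (sc$pct_at_min - sc$pct_at_max) %% 100
      )
    }
  }
  if (length(rows) == 0L) empty else dplyr::bind_rows(rows)
}

#' Ground-truth walking labels for FFT blocks
#'
#' Labels each complete analysis block of a recording as walking when more
#' than half of the block overlaps a scheduled bout -- the reference against
#' which block-level detection accuracy is scored.
#'
#' @param bouts Bout tibble (`start_s`, `duration_s`).
#' @param duration_s Recording duration in seconds.
#' @param cfg A [gait_config()] (block length).
#' @return A tibble: `start`, `end`, `walking_true`.
#' @export
bout_block_labels <- function(bouts, duration_s, cfg = gait_config()) {
  n_full <- floor(duration_s / cfg$block_seconds)
  starts <- (seq_len(n_full) - 1L) * cfg$block_seconds
  overlap <- vapply(starts, function(s0) {
    e0 <- s0 + cfg$block_seconds
    sum(pmax(0, pmin(e0, bouts$start_s + bouts$duration_s) -
                  pmax(s0, bouts$start_s)))
  }, numeric(1))
  tibble::tibble(start = starts, end = starts + cfg$block_seconds,
                 walking_true = overlap > cfg$block_seconds / 2)
}
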