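#' Gait detection and cycle-extraction configuration
#'
#' @param block_seconds FFT block duration in seconds (default 5; a 5-s block
#'   gives 0.2 Hz frequency resolution).
#' @param walk_band Closed frequency interval in Hz whose dominant spectral
#'   peak marks walking (default `c(2.5, 4.0)`, the forelimb rhythm band).
#' @param min_freq_hz Spectral bins below this frequency (and DC) are excluded
#'   from the peak search (default 0.4 Hz).
#' @param min_peak_prominence Minimum prominence in degrees for a hip
#'   flexion peak to delimit a gait cycle (default 5).
#' @param cycle_duration_bounds Admissible gait-cycle durations in seconds
#'   (default `c(0.4, 2.0)`).
#' @param cycles_per_session Number of valid cycles retained per session,
#'   chronological (default 10).
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(block_seconds = 5, walk_band = c(2.5, 4.0),
                        min_freq_hz = 0.4, min_peak_prominence = 5,
                        cycle_duration_bounds = c(0.4, 2.0),
                        cycles_per_session = 10) {
  stopifnot(block_seconds > 0, length(walk_band) == 2L,
            walk_band[1] < walk_band[2],
            length(cycle_duration_bounds) == 2L,
            all(cycle_duration_bounds > 0),
            cycle_duration_bounds[1] < cycle_duration_bounds[2])
  structure(list(block_seconds = block_seconds, walk_band = walk_band,
                 min_freq_hz = min_freq_hz,
                 min_peak_prominence = min_peak_prominence,
                 cycle_duration_bounds = cycle_duration_bounds,
                 cycles_per_session = cycles_per_session),
            class = "gait_config")
}

#' Block-wise dominant-frequency table
#'
#' Splits a channel into consecutive non-overlapping blocks, applies an FFT
#' (rectangular window) to each, and records the frequency of the peak
#' spectral magnitude after excluding DC and bins below `min_freq_hz`. A
#' block is a walking block iff that dominant frequency falls inside the
#' closed walking band.
#'
#' @param channel A [signal_channel()]; expected to be resampled to 1 kHz and
#'   low-pass filtered (10 Hz) upstream.
#' @param cfg A [gait_config()].
#' @return A tibble with one row per complete block: `start`, `end` (s),
#'   `dominant_frequency` (Hz), `peak_magnitude`, `walking` (logical).
#' @export
walking_blocks <- function(channel, cfg = gait_config()) {
  stopifnot(inherits(channel, "signal_channel"))
  n_block <- round(cfg$block_seconds * channel$rate)
  n_full <- floor(length(channel$samples) / n_block)
  if (n_full == 0L) {
    warn("Channel shorter than one FFT block: no walking analysis possible.",
         class = "pigait_warning_short")
    return(tibble::tibble(start = numeric(), end = numeric(),
                          dominant_frequency = numeric(),
                          peak_magnitude = numeric(), walking = logical()))
  }
  freqs <- (seq_len(n_block) - 1L) / cfg$block_seconds
  keep <- freqs >= cfg$min_freq_hz & freqs <= channel$rate / 2
  purrr::map_dfr(seq_len(n_full), function(b) {
    idx <- ((b - 1L) * n_block + 1L):(b * n_block)
    spec <- Mod(fft(channel$samples[idx]))
    i <- which(keep)[which.max(spec[keep])]
    f <- freqs[i]
    tibble::tibble(
      start = channel$start_time + (b - 1L) * cfg$block_seconds,
      end = channel$start_time + b * cfg$block_seconds,
      dominant_frequency = f,
      peak_magnitude = spec[i],
      walking = f >= cfg$walk_band[1] & f <= cfg$walk_band[2]
    )
  })
}

#' Detect walking intervals from thoracic medio-lateral acceleration
#'
#' The thoracic sensor captures the forelimb rhythm, identifiable in every
#' session even when hindlimb movement is absent. Adjacent walking blocks are
#' merged into intervals; an interval's dominant frequency is that of its
#' strongest block.
#'
#' @inheritParams walking_blocks
#' @return A tibble of intervals: `start`, `end` (s), `dominant_frequency`
#'   (Hz), `n_blocks`.
#' @export
detect_walking <- function(channel, cfg = gait_config()) {
  blocks <- walking_blocks(channel, cfg)
  wb <- blocks[blocks$walking, , drop = FALSE]
  if (nrow(wb) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          dominant_frequency = numeric(),
                          n_blocks = integer()))
  }
  run <- cumsum(c(TRUE, diff(wb$start) > cfg$block_seconds + 1e-9))
  wb |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      dominant_frequency = .data$dominant_frequency[which.max(.data$peak_magnitude)],
      n_blocks = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select("start", "end", "dominant_frequency", "n_blocks")
}

#' Session eligibility for gait-cycle analysis
#'
#' A session enters kinematic analysis only if the animal achieved at least
#' three reciprocating hindlimb gait cycles, which behaviourally corresponds
#' to a PTIBS score above 3.
#'
#' @param ptibs_score Aggregated PTIBS score for the session.
#' @param n_cycles_available Number of valid segmented cycles.
#' @return Logical.
#' @export
gait_eligibility <- function(ptibs_score, n_cycles_available) {
  isTRUE(ptibs_score > 3) && isTRUE(n_cycles_available >= 3)
}

# local maxima with topographic prominence >= min_prom; returns indices
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  # plateau handling: keep first index of flat-topped maxima
  if (length(cand) == 0L) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left to the first sample higher than the peak (or the edge)
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= min_prom]
}

#' Segment gait cycles from a hip-angle channel
#'
#' Cycles are delimited by consecutive peak-flexion events: local maxima of
#' the (already low-pass filtered) hip angle with prominence at least
#' `min_peak_prominence`, restricted to detected walking intervals. Cycles
#' with durations outside `cycle_duration_bounds` are discarded, and the
#' first `cycles_per_session` valid cycles (chronological) are retained.
#'
#' @param hip_angle A [signal_channel()] in degrees, 10 Hz low-pass filtered.
#' @param intervals Walking intervals from [detect_walking()]; `NULL` uses
#'   the whole channel.
#' @param cfg A [gait_config()].
#' @param side `"left"` or `"right"`, carried through to outputs.
#' @return A tibble with one row per retained cycle: `cycle`, `side`,
#'   `start_s`, `end_s`, `duration_s` and a list-column `samples` holding the
#'   raw angle samples from peak to peak (inclusive).
#' @export
segment_cycles <- function(hip_angle, intervals = NULL, cfg = gait_config(),
                           side = "left") {
  stopifnot(inherits(hip_angle, "signal_channel"))
  tt <- channel_times(hip_angle)
  use <- rep(is.null(intervals), length(tt))
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    for (k in seq_len(nrow(intervals))) {
      use <- use | (tt >= intervals$start[k] - 1e-9 &
                      tt <= intervals$end[k] + 1e-9)
    }
  }
  peaks <- find_peaks(hip_angle$samples, cfg$min_peak_prominence)
  peaks <- peaks[use[peaks]]
  out <- tibble::tibble(cycle = integer(), side = character(),
                        start_s = numeric(), end_s = numeric(),
                        duration_s = numeric(), samples = list())
  if (length(peaks) >= 2L) {
    rows <- list()
    for (k in seq_len(length(peaks) - 1L)) {
      i0 <- peaks[k]; i1 <- peaks[k + 1L]
      dur <- (i1 - i0) / hip_angle$rate
      # both delimiting peaks must lie in the same walking interval span
      if (dur < cfg$cycle_duration_bounds[1] ||
          dur > cfg$cycle_duration_bounds[2]) next
      if (!all(use[i0:i1])) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        side = side, start_s = tt[i0], end_s = tt[i1], duration_s = dur,
        samples = list(hip_angle$samples[i0:i1])
      )
      if (length(rows) >= cfg$cycles_per_session) break
    }
    if (length(rows) > 0L) {
      out <- dplyr::bind_rows(rows)
      out <- dplyr::mutate(out, cycle = dplyr::row_number(),
                           .before = "side")
    }
  }
  attr(out, "rate") <- hip_angle$rate
  out
}

#' Time-normalize a gait cycle to 101 points
#'
#' Linear interpolation of the raw cycle onto 101 evenly spaced time
#' fractions, 0 to 100% of the cycle, so cycles of different durations can be
#' averaged point by point.
#'
#' @param samples Numeric vector of raw cycle samples (>= 4) or a one-cycle
#'   row's `samples` entry from [segment_cycles()].
#' @return A tibble of class `normalized_gait_cycle` with columns `pct`
#'   (0..100) and `angle` (degrees).
#' @export
normalize_cycle <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 4L) {
    abort("A gait cycle needs at least 4 samples to interpolate.",
          class = "pigait_error_parameter")
  }
  pct_in <- seq(0, 100, length.out = length(x))
  y <- approx(pct_in, x, xout = 0:100)$y
  structure(tibble::tibble(pct = 0:100, angle = y),
            class = c("normalized_gait_cycle", class(tibble::tibble())))
}

#' Scalar kinematic metrics of a normalized gait cycle
#'
#' Maximum angle (peak hip flexion), minimum angle (peak hip extension),
#' range of motion (ROM = max - min), and the gait-cycle percentages at which
#' the extrema occur (first occurrence on ties).
#'
#' @param nc A `normalized_gait_cycle` (101-point tibble) or numeric vector
#'   of 101 angles.
#' @return A one-row tibble: `max_angle`, `min_angle`, `rom`, `pct_at_max`,
#'   `pct_at_min`.
#' @export
cycle_metrics <- function(nc) {
  ang <- if (is.data.frame(nc)) nc$angle else as.numeric(nc)
  stopifnot(length(ang) == 101L)
  imax <- which.max(ang)
  imin <- which.min(ang)
  tibble::tibble(
    max_angle = ang[imax], min_angle = ang[imin],
    rom = ang[imax] - ang[imin],
    pct_at_max = imax - 1, pct_at_min = imin - 1
  )
}

#' Representative gait cycle and averaged metrics
#'
#' Point-wise mean and SEM across the session's normalized cycles, plus the
#' mean of the per-cycle scalar metrics. Metrics are averaged over cycles,
#' never re-extracted from the mean curve: asynchronous peaks would bias the
#' extrema of the averaged curve downward.
#'
#' @param cycles List of `normalized_gait_cycle` objects (or a list of
#'   101-point numeric vectors).
#' @return A list of class `representative_cycle`: `curve` (tibble `pct`,
#'   `mean_angle`, `sem_angle`), `metrics` (one-row tibble of averaged
#'   metrics) and `n_cycles`.
#' @export
representative_cycle <- function(cycles) {
  if (length(cycles) == 0L) {
    abort("Need at least one cycle.", class = "pigait_error_parameter")
  }
  mat <- vapply(cycles, function(c) {
    if (is.data.frame(c)) c$angle else as.numeric(c)
  }, numeric(101L))
  mat <- matrix(mat, nrow = 101L)
  per_cycle <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    cycle_metrics(mat[, j])
  })
  structure(list(
    curve = tibble::tibble(
      pct = 0:100,
      mean_angle = rowMeans(mat),
      sem_angle = apply(mat, 1L, sem)
    ),
    metrics = dplyr::summarise(per_cycle,
                               dplyr::across(dplyr::everything(), mean)),
    per_cycle = per_cycle,
    n_cycles = ncol(mat)
  ), class = "representative_cycle")
}

#' @export
print.representative_cycle <- function(x, ...) {
  cat(sprintf("<representative_cycle> mean of %d cycles\n", x$n_cycles))
  print(x$metrics)
  invisible(x)
}

#' Tidy a representative cycle into its mean +/- SEM curve
#' @param x A [representative_cycle()].
#' @param ... Unused.
#' @return The 101-row curve tibble.
#' @method tidy representative_cycle
#' @export
tidy.representative_cycle <- function(x, ...) x$curve

#' One-row summary of a representative cycle
#' @param x A [representative_cycle()].
#' @param ... Unused.
#' @return The averaged metrics tibble with `n_cycles`.
#' @method glance representative_cycle
#' @export
glance.representative_cycle <- function(x, ...) {
  dplyr::mutate(x$metrics, n_cycles = x$n_cycles)
}

#' Gait-metric changes relative to Baseline
#'
#' Angle terms (`max_angle`, `min_angle`, `rom`) are relative percentage
#' changes, `100 * (post - base) / base` with the signed baseline in the
#' denominator, so that a shrinking extension (a negative angle moving toward
#' zero) is a negative change in extension; timing terms are percentage-point
#' shifts `post - base` within the gait cycle, negative meaning the extremum
#' is reached earlier.
#'
#' @param post,base One-row metric tibbles from [cycle_metrics()] or
#'   [representative_cycle()]`$metrics`.
#' @return A one-row tibble: `d_max_pct`, `d_min_pct`, `d_rom_pct`,
#'   `d_pct_at_max`, `d_pct_at_min`. Relative terms with a zero baseline
#'   denominator are NA with a warning.
#' @export
gait_delta <- function(post, base) {
  rel <- function(p, b) {
    if (!is.finite(b) || b == 0) {
      warn("Zero baseline value: relative delta undefined.",
           class = "pigait_warning_baseline")
      return(NA_real_)
    }
    100 * (p - b) / b
  }
  tibble::tibble(
    d_max_pct = rel(post$max_angle, base$max_angle),
    d_min_pct = rel(post$min_angle, base$min_angle),
    d_rom_pct = rel(post$rom, base$rom),
    d_pct_at_max = post$pct_at_max - base$pct_at_max,
    d_pct_at_min = post$pct_at_min - base$pct_at_min
  )
}

#' Full gait analysis of one session recording
#'
#' Thoracic medio-lateral channel is resampled to the goniometer rate and
#' low-pass filtered, walking intervals are detected, and each hip channel is
#' filtered, segmented into cycles, normalized and summarised.
#'
#' @param session A [session_recording()] with a thoracic triad and at least
#'   one hip channel.
#' @param cfg A [gait_config()].
#' @param target_rate Common analysis rate in Hz (default 1000).
#' @return A list of class `gait_session_result`: `intervals`, and per-side
#'   lists with `cycles` (segmentation tibble), `normalized` (list of
#'   101-point cycles) and `representative` (or `NULL` when fewer than 3
#'   valid cycles were found).
#' @export
analyze_gait_session <- function(session, cfg = gait_config(),
                                 target_rate = 1000) {
  stopifnot(inherits(session, "session_recording"))
  if (is.null(session$thoracic)) {
    abort("Gait analysis needs the thoracic IMU triad.",
          class = "pigait_error_data")
  }
  ml <- triad_role(session$thoracic, "medio_lateral")
  ml <- resample_signal(ml, target_rate)
  ml <- butterworth_lowpass(ml, order = 4, cutoff_hz = 10)
  intervals <- detect_walking(ml, cfg)
  one_side <- function(hip, side) {
    if (is.null(hip)) return(NULL)
    hip <- resample_signal(hip, target_rate)
    hip <- butterworth_lowpass(hip, order = 4, cutoff_hz = 10)
    cyc <- segment_cycles(hip, intervals, cfg, side = side)
    norm <- purrr::map(cyc$samples, normalize_cycle)
    rep <- if (nrow(cyc) >= 3L) representative_cycle(norm) else NULL
    list(cycles = cyc, normalized = norm, representative = rep)
  }
  structure(list(
    animal = session$animal_id, group = session$group,
    session = session$session, intervals = intervals,
    left = one_side(session$hip_left, "left"),
    right = one_side(session$hip_right, "right")
  ), class = "gait_session_result")
}
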