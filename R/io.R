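#' Read a delimited signal file
#'
#' Sessions are stored as delimited text (comma or tab, auto-detected), one
#' header row, a `time_s` column (seconds, 0-based at recording start) and one
#' column per channel. Time must be strictly increasing and near-uniform: the
#' rate is inferred from the median time step, steps deviating from it by more
#' than the tolerance are rejected (gaps are not imputed -- block-wise FFT
#' logic downstream assumes uniform sampling).
#'
#' @param path File path.
#' @param time_col Name of the time column (default `"time_s"`).
#' @param nominal_rate Optional nominal rate in Hz; a warning is recorded if
#'   the inferred rate deviates from it by more than 1%.
#' @param tol Relative non-uniformity tolerance on time steps (default 0.01).
#' @return A named list of [signal_channel()] objects, one per non-time
#'   column, with an attribute `rate`.
#' @export
read_signal_channels <- function(path, time_col = "time_s",
                                 nominal_rate = NULL, tol = 0.01,
                                 units = "deg/s^2") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "pigait_error_schema")
  }
  df <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                          progress = FALSE)
  if (!time_col %in% names(df)) {
    abort(sprintf("Missing required time column '%s' in %s.", time_col, path),
          class = "pigait_error_schema")
  }
  chan_cols <- setdiff(names(df), time_col)
  if (length(chan_cols) == 0L) {
    abort(sprintf("No channel columns in %s.", path),
          class = "pigait_error_schema")
  }
  tt <- df[[time_col]]
  if (length(tt) < 2L) {
    abort("Cannot infer a sampling rate from fewer than two samples.",
          class = "pigait_error_data")
  }
  dt <- diff(tt)
  if (any(dt <= 0)) {
    abort(sprintf("Time column in %s is not strictly increasing.", path),
          class = "pigait_error_data")
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > tol * step)) {
    abort(sprintf("Non-uniform sampling in %s (gap beyond %g%% of the median step).",
                  path, 100 * tol), class = "pigait_error_data")
  }
  rate <- 1 / step
  if (!is.null(nominal_rate) && abs(rate - nominal_rate) > 0.01 * nominal_rate) {
    warn(sprintf("Inferred rate %.6g Hz deviates >1%% from nominal %g Hz in %s.",
                 rate, nominal_rate, path), class = "pigait_warning_rate")
  }
  out <- lapply(chan_cols, function(cn) {
    signal_channel(df[[cn]], rate = rate, units = units, axis = cn,
                   start_time = tt[1L])
  })
  names(out) <- chan_cols
  attr(out, "rate") <- rate
  out
}

sniff_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Write channels to a delimited signal file
#'
#' Round-trips the format read by [read_signal_channels()].
#'
#' @param channels Named list of [signal_channel()] sharing rate and length.
#' @param path Output file path (`.csv` comma, `.tsv` tab).
#' @return `path`, invisibly.
#' @export
write_signal_channels <- function(channels, path) {
  rates <- vapply(channels, function(c) c$rate, numeric(1))
  lens <- vapply(channels, function(c) length(c$samples), integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L) {
    abort("All channels must share rate and length to share a time grid.",
          class = "pigait_error_data")
  }
  t0 <- channels[[1L]]$start_time
  df <- c(list(time_s = t0 + (seq_len(lens[1L]) - 1L) / rates[1L]),
          lapply(channels, function(c) c$samples))
  df <- tibble::as_tibble(df)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Load one session recording from delimited files
#'
#' @param paths Named list with any of `imu_thoracic`, `imu_lumbar`,
#'   `goniometer` file paths; missing entries yield `NULL` slots.
#' @param animal_id,group,session Session metadata (see [session_recording()]).
#' @param schema Channel-name schema: a list with `imu_axes` (names of the
#'   x/y/z angular-acceleration columns), `axis_map` (anatomical roles, see
#'   [imu_triad()]), and `hip_cols` (left/right flexion-extension column
#'   names). Defaults match the files written by [generate_study()].
#' @param nominal_imu_rate,nominal_gonio_rate Nominal rates (Hz) used for the
#'   1% rate-deviation check.
#' @return A [session_recording()].
#' @export
load_session <- function(paths, animal_id, group, session,
                         schema = default_schema(),
                         nominal_imu_rate = 2000, nominal_gonio_rate = 1000) {
  read_triad <- function(path, placement) {
    if (is.null(path)) return(NULL)
    chans <- read_signal_channels(path, nominal_rate = nominal_imu_rate,
                                  units = "deg/s^2")
    need <- unlist(schema$imu_axes)
    if (!all(need %in% names(chans))) {
      abort(sprintf("IMU file %s lacks columns: %s", path,
                    paste(setdiff(need, names(chans)), collapse = ", ")),
            class = "pigait_error_schema")
    }
    imu_triad(chans[[schema$imu_axes$x]], chans[[schema$imu_axes$y]],
              chans[[schema$imu_axes$z]], placement = placement,
              axis_map = schema$axis_map)
  }
  hipL <- hipR <- NULL
  if (!is.null(paths$goniometer)) {
    gch <- read_signal_channels(paths$goniometer,
                                nominal_rate = nominal_gonio_rate,
                                units = "deg")
    need <- unlist(schema$hip_cols)
    if (!all(need %in% names(gch))) {
      abort(sprintf("Goniometer file %s lacks columns: %s", paths$goniometer,
                    paste(setdiff(need, names(gch)), collapse = ", ")),
            class = "pigait_error_schema")
    }
    hipL <- gch[[schema$hip_cols$left]]
    hipR <- gch[[schema$hip_cols$right]]
  }
  session_recording(
    animal_id = animal_id, group = group, session = session,
    thoracic = read_triad(paths$imu_thoracic, "thoracic_T4"),
    lumbar = read_triad(paths$imu_lumbar, "lumbar_L3"),
    hip_left = hipL, hip_right = hipR
  )
}

#' Default channel-name schema for session files
#' @return A schema list (see [load_session()]).
#' @export
default_schema <- function() {
  list(
    imu_axes = list(x = "ang_acc_x", y = "ang_acc_y", z = "ang_acc_z"),
    axis_map = list(yaw = "z", medio_lateral = "y"),
    hip_cols = list(left = "hip_left", right = "hip_right")
  )
}
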