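#' Uniformly sampled signal channel
#'
#' The atom every filter and transform in the package consumes: an ordered
#' numeric series with a sampling rate, physical units and an anatomical axis
#' label. Filtering and resampling operations preserve `units` and `axis`.
#'
#' @param samples Numeric vector of sample values (length >= 1, no NA).
#' @param rate Sampling rate in Hz, strictly positive.
#' @param units Physical units, one of `"deg/s^2"` (angular acceleration),
#'   `"deg"` (joint angle) or `"m/s^2"` (linear acceleration).
#' @param axis Axis / channel label, e.g. `"medio-lateral"` or
#'   `"dorsal-plane-rotational"`.
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `signal_channel`.
#' @examples
#' ch <- signal_channel(sin(2 * pi * 3 * seq(0, 1, by = 1e-3)), rate = 1000,
#'                      units = "deg", axis = "hip flexion/extension")
#' channel_duration(ch)
#' @export
signal_channel <- function(samples, rate,
                           units = c("deg/s^2", "deg", "m/s^2"),
                           axis = "", start_time = 0) {
  units <- match.arg(units)
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a numeric vector with at least one value.",
          class = "pigait_error_parameter")
  }
  if (anyNA(samples)) {
    abort("`samples` must not contain missing values.",
          class = "pigait_error_data")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).",
          class = "pigait_error_parameter")
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         units = units, axis = as.character(axis)[1L],
         start_time = as.numeric(start_time)[1L]),
    class = "signal_channel"
  )
}

#' @export
length.signal_channel <- function(x) length(x$samples)

#' Duration of a channel in seconds
#'
#' `(n - 1) / rate`: the time spanned between first and last sample.
#' @param x A [signal_channel()].
#' @return Duration in seconds.
#' @export
channel_duration <- function(x) {
  stopifnot(inherits(x, "signal_channel"))
  (length(x$samples) - 1L) / x$rate
}

#' Sample times of a channel
#' @param x A [signal_channel()].
#' @return Numeric vector of times in seconds.
#' @export
channel_times <- function(x) {
  stopifnot(inherits(x, "signal_channel"))
  x$start_time + (seq_along(x$samples) - 1L) / x$rate
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel> %d samples @ %g Hz [%s] axis=%s, t0=%g s\n",
              length(x$samples), x$rate, x$units, x$axis, x$start_time))
  invisible(x)
}

#' @export
as.data.frame.signal_channel <- function(x, ...) {
  as.data.frame(tidy.signal_channel(x))
}

#' Tidy a signal channel into a (time, value) tibble
#'
#' @param x A [signal_channel()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `value`.
#' @method tidy signal_channel
#' @export
tidy.signal_channel <- function(x, ...) {
  tibble::tibble(
    time_s = x$start_time + (seq_along(x$samples) - 1L) / x$rate,
    value = x$samples
  )
}

# clone a channel with new samples (and optionally new rate), keeping metadata
channel_like <- function(template, samples, rate = template$rate,
                         start_time = template$start_time) {
  signal_channel(samples, rate, units = template$units, axis = template$axis,
                 start_time = start_time)
}

#' Tri-axial IMU channel set
#'
#' Three orthogonal angular-acceleration channels from one trunk-mounted
#' inertial measurement unit, with an axis map declaring which device axis
#' corresponds to which anatomical role. The `yaw` role (rotation parallel to
#' the dorsal plane, i.e. the animal turning left or right) drives activity
#' quantification; the `medio_lateral` role drives walking detection.
#'
#' @param x,y,z [signal_channel()] objects in `deg/s^2`, equal rate and length.
#' @param placement Sensor landmark: `"thoracic_T4"` or `"lumbar_L3"`.
#' @param axis_map Named list mapping roles (`yaw`, `medio_lateral`) to one of
#'   `"x"`, `"y"`, `"z"`.
#' @return An object of class `imu_triad`.
#' @export
imu_triad <- function(x, y, z, placement = c("thoracic_T4", "lumbar_L3"),
                      axis_map = list(yaw = "z", medio_lateral = "y")) {
  placement <- match.arg(placement)
  chans <- list(x = x, y = y, z = z)
  ok <- vapply(chans, inherits, logical(1), "signal_channel")
  if (!all(ok)) abort("All triad channels must be signal_channel objects.",
                      class = "pigait_error_parameter")
  rates <- vapply(chans, function(c) c$rate, numeric(1))
  lens <- vapply(chans, function(c) length(c$samples), integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L) {
    abort("Triad channels must share rate and length.",
          class = "pigait_error_data")
  }
  if (!all(unlist(axis_map) %in% c("x", "y", "z"))) {
    abort("`axis_map` values must be one of 'x', 'y', 'z'.",
          class = "pigait_error_config")
  }
  structure(list(channels = chans, placement = placement, axis_map = axis_map),
            class = "imu_triad")
}

#' @export
print.imu_triad <- function(x, ...) {
  cat(sprintf("<imu_triad> placement=%s, %d samples @ %g Hz\n",
              x$placement, length(x$channels$x$samples), x$channels$x$rate))
  invisible(x)
}

# pull the channel playing a given anatomical role out of a triad
triad_role <- function(imu, role) {
  key <- imu$axis_map[[role]]
  if (is.null(key)) {
    abort(sprintf("Axis map lacks a '%s' assignment.", role),
          class = "pigait_error_config")
  }
  imu$channels[[key]]
}

#' One animal x one session recording
#'
#' Bundles the two IMU triads (thoracic T4, lumbar L3), the left/right hip
#' electro-goniometer channels (0 degrees = upright anatomical reference,
#' flexion positive, extension negative) and session metadata for one of the
#' three design points: Baseline (2 days pre-injury), Post2d and Post14d.
#' Goniometer channels may be `NULL` for unsupervised activity sessions
#' recorded without goniometers.
#'
#' @param animal_id Animal identifier (character).
#' @param group `"DAMAGED"` or `"CONTROL"`.
#' @param session `"Baseline"`, `"Post2d"` or `"Post14d"`.
#' @param thoracic,lumbar [imu_triad()] objects (either may be `NULL`).
#' @param hip_left,hip_right [signal_channel()] hip angle channels in `deg`,
#'   or `NULL`.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(animal_id, group = c("DAMAGED", "CONTROL"),
                              session = c("Baseline", "Post2d", "Post14d"),
                              thoracic = NULL, lumbar = NULL,
                              hip_left = NULL, hip_right = NULL) {
  group <- match.arg(group)
  session <- match.arg(session)
  for (im in list(thoracic, lumbar)) {
    if (!is.null(im) && !inherits(im, "imu_triad"))
      abort("IMU slots must be imu_triad or NULL.",
            class = "pigait_error_parameter")
  }
  for (hp in list(hip_left, hip_right)) {
    if (!is.null(hp) && !inherits(hp, "signal_channel"))
      abort("Hip slots must be signal_channel or NULL.",
            class = "pigait_error_parameter")
  }
  structure(
    list(animal_id = as.character(animal_id), group = group, session = session,
         thoracic = thoracic, lumbar = lumbar,
         hip_left = hip_left, hip_right = hip_right),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  has <- function(s) if (is.null(x[[s]])) "-" else "+"
  cat(sprintf("<session_recording> %s / %s / %s  [thoracic%s lumbar%s hipL%s hipR%s]\n",
              x$animal_id, x$group, x$session,
              has("thoracic"), has("lumbar"), has("hip_left"), has("hip_right")))
  invisible(x)
}
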