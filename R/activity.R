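#' Activity intensity thresholds
#'
#' Bin edges for the three activity intensity levels of the dorsal-plane
#' angular-acceleration magnitude: Rest (recumbency) below `rest_upper`,
#' Low (low-impact activities such as walking) up to `low_upper`, High
#' (high-impact activities such as playing) above. Defaults 5 and 50 deg/s^2.
#'
#' @param rest_upper Upper edge of the Rest bin in deg/s^2 (default 5).
#' @param low_upper Upper edge of the Low bin in deg/s^2 (default 50).
#' @return A list of class `activity_thresholds`.
#' @export
activity_thresholds <- function(rest_upper = 5, low_upper = 50) {
  if (!(rest_upper > 0 && low_upper > rest_upper)) {
    abort("Thresholds must satisfy 0 < rest_upper < low_upper.",
          class = "pigait_error_parameter")
  }
  structure(list(rest_upper = rest_upper, low_upper = low_upper),
            class = "activity_thresholds")
}

#' Dorsal-plane angular-acceleration magnitude
#'
#' Smooths the yaw-axis channel (rotation parallel to the dorsal plane: the
#' animal turning left or right) with a Savitzky-Golay filter and takes the
#' absolute value. This magnitude is what gets binned into intensity levels.
#'
#' @param imu An [imu_triad()] whose axis map assigns the `yaw` role.
#' @param poly_order,frame_seconds Savitzky-Golay parameters, see
#'   [savgol_filter()].
#' @return A [signal_channel()] of non-negative magnitudes in deg/s^2.
#' @export
dorsal_plane_magnitude <- function(imu, poly_order = 3, frame_seconds = 0.051) {
  stopifnot(inherits(imu, "imu_triad"))
  yaw <- triad_role(imu, "yaw")
  sm <- savgol_filter(yaw, poly_order = poly_order, frame_seconds = frame_seconds)
  channel_like(sm, abs(sm$samples))
}

#' Classify magnitude samples into intensity levels
#'
#' Half-open partition: Rest = \[0, rest_upper), Low = \[rest_upper,
#' low_upper), High = \[low_upper, Inf). A value exactly at `rest_upper` is
#' non-rest (Low); a value exactly at `low_upper` is High.
#'
#' @param mag A [signal_channel()] of non-negative magnitudes, or a numeric
#'   vector.
#' @param thr An [activity_thresholds()].
#' @return A factor with levels `Rest`, `Low`, `High`, one per sample.
#' @export
classify_intensity <- function(mag, thr = activity_thresholds()) {
  x <- if (inherits(mag, "signal_channel")) mag$samples else as.numeric(mag)
  if (any(x < 0)) {
    abort("Negative magnitude sample: upstream must take the absolute value.",
          class = "pigait_error_internal")
  }
  cut(x, breaks = c(-Inf, thr$rest_upper, thr$low_upper, Inf),
      labels = c("Rest", "Low", "High"), right = FALSE)
}

#' Fractions of time per intensity level
#'
#' @param labels Factor from [classify_intensity()].
#' @return A one-row tibble with `fraction_rest`, `fraction_low`,
#'   `fraction_high` (percent of time, summing to 100) and `non_rest_pct`.
#' @export
intensity_fractions <- function(labels) {
  if (length(labels) == 0L) {
    abort("Empty label sequence.", class = "pigait_error_parameter")
  }
  p <- 100 * table(factor(labels, levels = c("Rest", "Low", "High"))) /
    length(labels)
  tibble::tibble(
    fraction_rest = as.numeric(p[["Rest"]]),
    fraction_low = as.numeric(p[["Low"]]),
    fraction_high = as.numeric(p[["High"]]),
    non_rest_pct = as.numeric(p[["Low"]] + p[["High"]])
  )
}

#' Percentage of time in non-rest activity
#'
#' Non-rest activity -- magnitude at or above the rest threshold -- is the
#' general marker of physical activity.
#'
#' @param labels Factor from [classify_intensity()].
#' @return Percentage of samples labelled Low or High.
#' @export
non_rest_percentage <- function(labels) {
  intensity_fractions(labels)$non_rest_pct
}

#' Activity recovery relative to Baseline
#'
#' A session's non-rest percentage normalised to the mean of the animal's
#' Baseline non-rest percentages, expressed in percent (100 = at Baseline).
#' The change from Baseline is `recovery - 100`.
#'
#' @param session_non_rest Non-rest percentage of the session.
#' @param baseline_non_rest_values Numeric vector of Baseline non-rest
#'   percentages for the same animal and placement.
#' @return Recovery percentage.
#' @export
recovery_percentage <- function(session_non_rest, baseline_non_rest_values) {
  b <- mean(baseline_non_rest_values)
  if (!is.finite(b) || b <= 0) {
    warn("Baseline mean non-rest is zero: recovery undefined.",
         class = "pigait_warning_baseline")
    return(NA_real_)
  }
  100 * session_non_rest / b
}

#' Summarize activity for one session recording
#'
#' Runs the full activity pipeline for each available IMU placement:
#' Savitzky-Golay smoothing, dorsal-plane magnitude, intensity binning,
#' non-rest percentage and -- when Baseline values are supplied -- recovery.
#' Thoracic and lumbar sensors are binned separately.
#'
#' @param session A [session_recording()].
#' @param thr An [activity_thresholds()].
#' @param baseline_lookup Optional function `(animal_id, placement) ->`
#'   numeric vector of Baseline non-rest percentages; used for non-Baseline
#'   sessions.
#' @return A tibble with one row per available placement: `animal`, `group`,
#'   `session`, `placement`, the three bin fractions, `non_rest_pct`,
#'   `recovery_pct` (NA when not applicable).
#' @export
summarize_activity <- function(session, thr = activity_thresholds(),
                               baseline_lookup = NULL) {
  stopifnot(inherits(session, "session_recording"))
  slots <- list(thoracic = session$thoracic, lumbar = session$lumbar)
  present <- !vapply(slots, is.null, logical(1))
  if (!any(present)) {
    warn("No IMU triads in session: empty activity summary.",
         class = "pigait_warning_missing")
  }
  rows <- purrr::map(names(slots)[present], function(pl) {
    mag <- dorsal_plane_magnitude(slots[[pl]])
    fr <- intensity_fractions(classify_intensity(mag, thr))
    rec <- NA_real_
    if (session$session != "Baseline" && !is.null(baseline_lookup)) {
      base_vals <- baseline_lookup(session$animal_id, pl)
      if (length(base_vals) > 0) {
        rec <- recovery_percentage(fr$non_rest_pct, base_vals)
      }
    }
    dplyr::bind_cols(
      tibble::tibble(animal = session$animal_id, group = session$group,
                     session = session$session, placement = pl),
      fr, tibble::tibble(recovery_pct = rec)
    )
  })
  dplyr::bind_rows(rows)
}

#' Group-level activity summary
#'
#' Aggregates per-animal activity rows to group x session x placement means
#' with SEM (sample SD, n-1 denominator, over animals).
#'
#' @param activity_tbl Tibble from [summarize_activity()] rows combined over
#'   animals/sessions.
#' @return Tibble with mean and SEM of each fraction, non-rest and recovery.
#' @export
activity_group_summary <- function(activity_tbl) {
  activity_tbl |>
    dplyr::group_by(.data$group, .data$session, .data$placement) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        c("fraction_rest", "fraction_low", "fraction_high",
          "non_rest_pct", "recovery_pct"),
        list(mean = ~ mean(.x, na.rm = TRUE), sem = ~ sem(.x))
      ),
      .groups = "drop"
    )
}
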