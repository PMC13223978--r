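#' Two-group, three-session study design for the synthetic generator
#'
#' Defaults mirror the functional-evaluation design: three animals with a
#' full contusion-compression lesion (DAMAGED) and one with a lateralized
#' partial lesion (CONTROL), each recorded at Baseline, 2 days post-injury
#' and 14 days post-injury. Per-session effect parameters encode the
#' qualitative injury signature: collapsed non-rest activity and absent
#' hindlimb cycles at Post2d, partial recovery with reduced hip extension and
#' earlier peak flexion at Post14d.
#'
#' @param animals Tibble (`animal`, `group`).
#' @param activity_minutes Duration of the unsupervised activity recording
#'   per session, in minutes (default 30).
#' @param gait_seconds Duration of the corridor gait recording, in seconds
#'   (default 60).
#' @param effects Tibble with one row per group x session giving
#'   `frac_rest`, `frac_low`, `frac_high`, `hip_active`, `peak_flexion`,
#'   `peak_extension`, `pct_at_max`, `pct_at_min`, and `ptibs` (list-column
#'   of observer score vectors). `NULL` uses the built-in defaults.
#' @return A list of class `study_design`.
#' @export
study_design <- function(animals = tibble::tibble(
                           animal = c("P1", "P2", "P3", "P4"),
                           group = c("DAMAGED", "DAMAGED", "DAMAGED",
                                     "CONTROL")),
                         activity_minutes = 30, gait_seconds = 60,
                         effects = NULL) {
  if (is.null(effects)) effects <- default_effects()
  stopifnot(all(c("animal", "group") %in% names(animals)),
            all(animals$group %in% GROUP_LEVELS))
  structure(list(animals = animals, activity_minutes = activity_minutes,
                 gait_seconds = gait_seconds, effects = effects),
            class = "study_design")
}

default_effects <- function() {
  tibble::tribble(
    ~group,     ~session,   ~frac_rest, ~frac_low, ~frac_high, ~hip_active,
      ~peak_flexion, ~peak_extension, ~pct_at_max, ~pct_at_min, ~ptibs,
    "DAMAGED",  "Baseline", 0.55, 0.35, 0.10, TRUE,  25.0, -15.00, 40, 85,
      list(c(10L, 10L, 10L)),
    "DAMAGED",  "Post2d",   0.82, 0.15, 0.03, FALSE, NA,   NA,     NA, NA,
      list(c(1L, 1L, 1L)),
    "DAMAGED",  "Post14d",  0.60, 0.31, 0.09, TRUE,  24.3, -9.59,  30, 85,
      list(c(3L, 4L, 4L)),
    "CONTROL",  "Baseline", 0.55, 0.35, 0.10, TRUE,  25.0, -15.00, 40, 85,
      list(c(10L, 10L, 10L)),
    "CONTROL",  "Post2d",   0.85, 0.12, 0.03, FALSE, NA,   NA,     NA, NA,
      list(c(2L, 2L, 2L)),
    "CONTROL",  "Post14d",  0.58, 0.33, 0.09, TRUE,  27.0, -20.07, 41, 76,
      list(c(8L, 8L, 8L))
  )
}

#' Generate a full synthetic study on disk
#'
#' Writes, for every animal x session, an unsupervised activity recording
#' (two IMU files) and a corridor gait recording (two IMU files plus a
#' goniometer file), an observer-score table `ptibs.csv`, and a
#' `manifest.json` with the file map and the ground truth (scheduled
#' activity fractions, bout and cycle tables, per-session seeds) sufficient
#' to score every recovery metric without re-reading generator code.
#' Deterministic for a fixed master seed.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed; per-session seeds are derived from it.
#' @return The manifest, invisibly (also written as JSON).
#' @export
generate_study <- function(design = study_design(), dir, seed) {
  stopifnot(inherits(design, "study_design"))
  if (missing(seed)) abort("An explicit `seed` is required.",
                           class = "pigait_error_parameter")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- SESSION_LEVELS
  manifest <- list(seed = seed, sessions = list())
  ptibs_rows <- list()
  idx <- 0L
  for (ai in seq_len(nrow(design$animals))) {
    animal <- design$animals$animal[ai]
    group <- design$animals$group[ai]
    for (ses in sessions) {
      idx <- idx + 1L
      eff <- design$effects[design$effects$group == group &
                              design$effects$session == ses, ]
      stopifnot(nrow(eff) == 1L)
      s_act <- (seed + 1000L * idx + 1L) %% .Machine$integer.max
      s_gait <- (seed + 1000L * idx + 2L) %% .Machine$integer.max

      act_sc <- activity_scenario(
        epochs = epoch_schedule(
          total_s = design$activity_minutes * 60,
          fractions = c(rest = eff$frac_rest, low = eff$frac_low,
                        high = eff$frac_high))
      )
      act <- generate_activity_session(act_sc, animal_id = animal,
                                       group = group, session = ses,
                                       seed = s_act)
      gait_sc <- do.call(gait_scenario, c(
        list(duration_s = design$gait_seconds,
             bouts = default_bouts(design$gait_seconds),
             hip_active = eff$hip_active),
        if (eff$hip_active) list(peak_flexion = eff$peak_flexion,
                                 peak_extension = eff$peak_extension,
                                 pct_at_max = eff$pct_at_max,
                                 pct_at_min = eff$pct_at_min)
      ))
      gait <- generate_gait_session(gait_sc, animal_id = animal,
                                    group = group, session = ses,
                                    seed = s_gait)

      stem <- file.path(dir, paste0(animal, "_", ses))
      files <- list(
        activity_imu_thoracic = paste0(stem, "_activity_imu_thoracic.csv"),
        activity_imu_lumbar = paste0(stem, "_activity_imu_lumbar.csv"),
        gait_imu_thoracic = paste0(stem, "_gait_imu_thoracic.csv"),
        gait_imu_lumbar = paste0(stem, "_gait_imu_lumbar.csv"),
        gait_goniometer = paste0(stem, "_gait_goniometer.csv")
      )
      write_triad <- function(triad, path) {
        write_signal_channels(
          setNames(triad$channels[c("x", "y", "z")],
                   c("ang_acc_x", "ang_acc_y", "ang_acc_z")), path)
      }
      write_triad(act$session$thoracic, files$activity_imu_thoracic)
      write_triad(act$session$lumbar, files$activity_imu_lumbar)
      write_triad(gait$session$thoracic, files$gait_imu_thoracic)
      write_triad(gait$session$lumbar, files$gait_imu_lumbar)
      write_signal_channels(list(hip_left = gait$session$hip_left,
                                 hip_right = gait$session$hip_right),
                            files$gait_goniometer)

      manifest$sessions[[length(manifest$sessions) + 1L]] <- list(
        animal = animal, group = group, session = ses,
        files = lapply(files, basename),
        seeds = list(activity = s_act, gait = s_gait),
        truth = list(
          activity_fractions = as.list(attr(act$truth, "fractions")),
          gait_bouts = gait$truth$bouts,
          gait_cycles = gait$truth$cycles
        )
      )
      obs_scores <- unlist(eff$ptibs[[1]])
      ptibs_rows[[idx]] <- tibble::tibble(
        animal = animal, group = group, session = ses,
        observer = paste0("O", seq_along(obs_scores)),
        score = obs_scores
      )
    }
  }
  ptibs_tbl <- dplyr::bind_rows(ptibs_rows)
  readr::write_csv(ptibs_tbl, file.path(dir, "ptibs.csv"), progress = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# three mid-recording walking bouts scaled to the recording length
default_bouts <- function(duration_s) {
  if (duration_s >= 60) {
    tibble::tibble(start_s = c(5, 25, 45), duration_s = c(10, 10, 10))
  } else {
    len <- max(4, duration_s * 0.4)
    tibble::tibble(start_s = max(1, duration_s * 0.2), duration_s = len)
  }
}
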