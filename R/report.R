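#' Study analysis configuration
#'
#' @param study_dir Directory holding session files, `ptibs.csv` and
#'   `manifest.json` (the format written by [generate_study()]).
#' @param out_dir Output directory for exported tables (optional).
#' @param thresholds An [activity_thresholds()].
#' @param gait A [gait_config()].
#' @param ptibs_method Observer aggregation rule, `"mean"` or `"median"`.
#' @param seed Seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return A list of class `study_config`.
#' @export
study_config <- function(study_dir, out_dir = NULL,
                         thresholds = activity_thresholds(),
                         gait = gait_config(),
                         ptibs_method = "mean", seed = NULL) {
  structure(list(study_dir = study_dir, out_dir = out_dir,
                 thresholds = thresholds, gait = gait,
                 ptibs_method = ptibs_method, seed = seed),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' The configuration round-trips losslessly through YAML so runs can be
#' reproduced from the file alone.
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [study_config()] (read).
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  study_config(
    study_dir = x$study_dir, out_dir = x$out_dir,
    thresholds = activity_thresholds(x$thresholds$rest_upper,
                                     x$thresholds$low_upper),
    gait = gait_config(
      block_seconds = x$gait$block_seconds,
      walk_band = as.numeric(x$gait$walk_band),
      min_freq_hz = x$gait$min_freq_hz,
      min_peak_prominence = x$gait$min_peak_prominence,
      cycle_duration_bounds = as.numeric(x$gait$cycle_duration_bounds),
      cycles_per_session = x$gait$cycles_per_session),
    ptibs_method = x$ptibs_method, seed = x$seed
  )
}

config_as_list <- function(config) {
  list(study_dir = config$study_dir, out_dir = config$out_dir,
       thresholds = unclass(config$thresholds),
       gait = unclass(config$gait),
       ptibs_method = config$ptibs_method, seed = config$seed)
}

# stable hash of the analysis parameters for the provenance block; the
# data/output directories are locations, not parameters, and are excluded so
# the same analysis of the same data hashes identically wherever it lives
config_hash <- function(config) {
  pars <- config_as_list(config)
  pars$study_dir <- NULL
  pars$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(pars, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full functional-evaluation pipeline over a study directory
#'
#' For every session in the manifest: activity summaries for both IMU
#' placements (with recovery vs the animal's Baseline), gait analysis when
#' goniometer data exist and the session is eligible (aggregated PTIBS score
#' above 3 and at least three valid cycles), and PTIBS group summaries and
#' changes from Baseline. Per-session failures are caught, logged and
#' surfaced in the report without aborting other sessions.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report` with tibbles `activity`,
#'   `activity_groups`, `ptibs`, `ptibs_groups`, `ptibs_changes`,
#'   `gait_metrics`, `gait_deltas`, `cycle_curves`, a `log` tibble and a
#'   `provenance` list (config hash, seed, package version).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  manifest_path <- file.path(config$study_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json in %s.", config$study_dir),
          class = "pigait_error_schema")
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  log_rows <- list()
  note <- function(animal, session, stage, message) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      animal = animal, session = session, stage = stage, message = message)
  }

  # --- PTIBS ---------------------------------------------------------------
  ptibs_path <- file.path(config$study_dir, "ptibs.csv")
  ptibs <- ptibs_groups <- ptibs_changes <- NULL
  if (file.exists(ptibs_path)) {
    scores <- readr::read_csv(ptibs_path, show_col_types = FALSE,
                              progress = FALSE)
    ptibs <- ptibs_assess(scores, method = config$ptibs_method)
    ptibs_groups <- ptibs_group_summary(ptibs)
    ptibs_changes <- tryCatch(ptibs_change_from_baseline(ptibs),
                              error = function(e) {
                                note(NA, NA, "ptibs", conditionMessage(e))
                                NULL
                              })
  } else {
    note(NA, NA, "ptibs", "ptibs.csv absent: PTIBS section skipped")
  }

  # --- per-session activity and gait ---------------------------------------
  activity_rows <- list()
  gait_results <- list()
  for (entry in manifest$sessions) {
    animal <- entry$animal; ses <- entry$session; group <- entry$group
    fp <- function(key) {
      f <- entry$files[[key]]
      if (is.null(f)) NULL else file.path(config$study_dir, f)
    }
    act <- tryCatch({
      rec <- load_session(list(imu_thoracic = fp("activity_imu_thoracic"),
                               imu_lumbar = fp("activity_imu_lumbar")),
                          animal_id = animal, group = group, session = ses)
      summarize_activity(rec, thr = config$thresholds)
    }, error = function(e) {
      note(animal, ses, "activity", conditionMessage(e)); NULL
    })
    if (!is.null(act)) activity_rows[[length(activity_rows) + 1L]] <- act

    gpath <- fp("gait_goniometer")
    if (!is.null(gpath) && file.exists(gpath)) {
      gr <- tryCatch({
        rec <- load_session(list(imu_thoracic = fp("gait_imu_thoracic"),
                                 imu_lumbar = fp("gait_imu_lumbar"),
                                 goniometer = gpath),
                            animal_id = animal, group = group, session = ses)
        analyze_gait_session(rec, cfg = config$gait)
      }, error = function(e) {
        note(animal, ses, "gait", conditionMessage(e)); NULL
      })
      if (!is.null(gr)) gait_results[[length(gait_results) + 1L]] <- gr
    } else {
      note(animal, ses, "gait", "goniometer file absent: gait section skipped")
    }
  }
  activity <- dplyr::bind_rows(activity_rows)
  activity <- add_activity_recovery(activity)

  # --- gait tables, gated on eligibility -----------------------------------
  score_of <- function(animal, ses) {
    if (is.null(ptibs)) return(NA_real_)
    s <- ptibs$score[ptibs$animal == animal & ptibs$session == ses]
    if (length(s) == 1L) s else NA_real_
  }
  gait_metric_rows <- list()
  curve_rows <- list()
  for (gr in gait_results) {
    for (side in c("left", "right")) {
      res <- gr[[side]]
      if (is.null(res)) next
      n_cyc <- nrow(res$cycles)
      sc <- score_of(gr$animal, gr$session)
      eligible <- gait_eligibility(sc, n_cyc)
      if (!eligible) {
        note(gr$animal, gr$session, "gait",
             sprintf("%s hip not analysable (PTIBS %s, %d cycles)",
                     side, format(sc), n_cyc))
        next
      }
      gait_metric_rows[[length(gait_metric_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(animal = gr$animal, group = gr$group,
                       session = gr$session, side = side,
                       n_cycles = res$representative$n_cycles),
        res$representative$metrics
      )
      curve_rows[[length(curve_rows) + 1L]] <- dplyr::mutate(
        res$representative$curve, animal = gr$animal, group = gr$group,
        session = gr$session, side = side, .before = 1L)
    }
  }
  gait_metrics <- dplyr::bind_rows(gait_metric_rows)
  gait_deltas <- compute_gait_deltas(gait_metrics)

  structure(list(
    activity = activity,
    activity_groups = if (nrow(activity) > 0) activity_group_summary(activity),
    ptibs = ptibs, ptibs_groups = ptibs_groups, ptibs_changes = ptibs_changes,
    gait_metrics = gait_metrics, gait_deltas = gait_deltas,
    cycle_curves = dplyr::bind_rows(curve_rows),
    log = dplyr::bind_rows(log_rows),
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("pigait")))
  ), class = "study_report")
}

# recovery_pct for non-Baseline rows from the same table's Baseline rows
add_activity_recovery <- function(activity) {
  if (nrow(activity) == 0L) return(activity)
  base <- activity |>
    dplyr::filter(.data$session == "Baseline") |>
    dplyr::group_by(.data$animal, .data$placement) |>
    dplyr::summarise(baseline_non_rest = mean(.data$non_rest_pct),
                     .groups = "drop")
  activity |>
    dplyr::left_join(base, by = c("animal", "placement")) |>
    dplyr::mutate(
      recovery_pct = dplyr::if_else(
        .data$session == "Baseline", NA_real_,
        100 * .data$non_rest_pct / .data$baseline_non_rest)
    ) |>
    dplyr::select(-"baseline_non_rest")
}

# per animal x side: deltas of every post session against Baseline
compute_gait_deltas <- function(gait_metrics) {
  empty <- tibble::tibble(animal = character(), group = character(),
                          session = character(), side = character(),
                          d_max_pct = numeric(), d_min_pct = numeric(),
                          d_rom_pct = numeric(), d_pct_at_max = numeric(),
                          d_pct_at_min = numeric())
  if (nrow(gait_metrics) == 0L) return(empty)
  rows <- list()
  for (key in split(gait_metrics,
                    paste(gait_metrics$animal, gait_metrics$side))) {
    base <- key[key$session == "Baseline", ]
    if (nrow(base) != 1L) next
    for (i in which(key$session != "Baseline")) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        key[i, c("animal", "group", "session", "side")],
        gait_delta(key[i, ], base)
      )
    }
  }
  if (length(rows) == 0L) empty else dplyr::bind_rows(rows)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  activity rows: %d | gait metric rows: %d | ptibs rows: %d\n",
              nrow(x$activity), nrow(x$gait_metrics),
              if (is.null(x$ptibs)) 0L else nrow(x$ptibs)))
  cat(sprintf("  log entries: %d | config %s\n",
              nrow(x$log), x$provenance$config_hash))
  invisible(x)
}

#' One-row overview of a study report
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A one-row tibble of section sizes.
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_animals = length(unique(x$activity$animal)),
    n_activity_rows = nrow(x$activity),
    n_gait_rows = nrow(x$gait_metrics),
    n_ptibs_rows = if (is.null(x$ptibs)) 0L else nrow(x$ptibs),
    n_log = nrow(x$log)
  )
}

#' Figure-ready tables from a study report
#'
#' One tidy table per figure family: stacked-bar activity fractions,
#' activity recovery lines, PTIBS trajectories (per-animal traces plus group
#' mean), and mean +/- SEM normalized gait-cycle curves.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Optional directory; when given, each table is also written as
#'   CSV.
#' @return A named list of tibbles: `activity_stacked`, `recovery`,
#'   `ptibs_trajectories`, `cycle_curves`.
#' @export
export_figures_data <- function(report, dir = NULL) {
  stopifnot(inherits(report, "study_report"))
  activity_stacked <- report$activity |>
    tidyr::pivot_longer(
      c("fraction_rest", "fraction_low", "fraction_high"),
      names_to = "level", names_prefix = "fraction_",
      values_to = "pct_time")
  recovery <- report$activity |>
    dplyr::filter(!is.na(.data$recovery_pct)) |>
    dplyr::select("animal", "group", "session", "placement", "recovery_pct")
  ptibs_traj <- NULL
  if (!is.null(report$ptibs)) {
    grp <- report$ptibs_groups |>
      dplyr::transmute(animal = paste0("group:", .data$group),
                       .data$group, .data$session,
                       score = .data$mean_score, sem = .data$sem_score,
                       kind = "group_mean")
    ind <- report$ptibs |>
      dplyr::transmute(.data$animal, .data$group, .data$session,
                       .data$score, sem = NA_real_, kind = "animal")
    ptibs_traj <- dplyr::bind_rows(ind, grp)
  }
  out <- list(activity_stacked = activity_stacked, recovery = recovery,
              ptibs_trajectories = ptibs_traj,
              cycle_curves = report$cycle_curves)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]])) {
        readr::write_csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                         progress = FALSE)
      }
    }
  }
  out
}

#' Write the report body to disk deterministically
#'
#' Writes every report table as CSV plus a `summary.json` holding group
#' summaries and provenance. Output bytes depend only on the input data and
#' configuration (no timestamps), so identical config + seed reruns are
#' byte-identical.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("activity", "activity_groups", "ptibs", "ptibs_groups",
            "ptibs_changes", "gait_metrics", "gait_deltas", "cycle_curves",
            "log")
  written <- character()
  for (nm in tabs) {
    tab <- report[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, f, progress = FALSE)
    written <- c(written, f)
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(report$provenance, f, auto_unbox = TRUE, digits = NA)
  invisible(c(written, f))
}
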