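#' The 10-level PTIBS rubric
#'
#' The Porcine Thoracic Injury Behaviour Scale rates hindlimb function in 10
#' ordinal stages, from no active hindlimb movement (1) to normal ambulation
#' (10). Levels 1-3 are "dragging", 4-6 "stepping", 7-10 "walking". The
#' rubric ships as an editable JSON file; levels whose original wording is
#' not fully anchored here are flagged `provisional` so users can substitute
#' the source scale's descriptors.
#'
#' @param path Optional path to a rubric JSON file; defaults to the packaged
#'   rubric.
#' @return A tibble: `level` (1..10), `category`, `descriptor`,
#'   `provisional`.
#' @export
ptibs_rubric <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ptibs_rubric.json", package = "pigait")
  }
  raw <- jsonlite::fromJSON(path)
  tbl <- tibble::as_tibble(raw$levels)
  stopifnot(nrow(tbl) == 10L, identical(sort(tbl$level), 1:10))
  expected <- rep(c("dragging", "stepping", "walking"), c(3, 3, 4))
  if (!identical(tbl$category[order(tbl$level)], expected)) {
    abort("Rubric categories must partition levels 1-3/4-6/7-10.",
          class = "pigait_error_data")
  }
  dplyr::arrange(tbl, .data$level)
}

norm_key <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", x)
}

#' Look up a PTIBS level by behaviour descriptor
#'
#' @param descriptor_key Canonical behaviour descriptor (case and punctuation
#'   insensitive).
#' @param rubric Rubric tibble from [ptibs_rubric()].
#' @return A one-row tibble with `level` and `category`.
#' @export
score_level <- function(descriptor_key, rubric = ptibs_rubric()) {
  hit <- which(norm_key(rubric$descriptor) == norm_key(descriptor_key))
  if (length(hit) != 1L) {
    abort(paste0(
      "Unknown descriptor '", descriptor_key, "'. Valid descriptors:\n  ",
      paste(rubric$descriptor, collapse = "\n  ")),
      class = "pigait_error_lookup")
  }
  rubric[hit, c("level", "category")]
}

#' Aggregate blinded observer scores
#'
#' Sessions are scored from video by independent observers blinded to group
#' and session; the per-animal session score is their mean (default) or
#' median.
#'
#' @param scores Integer observer scores, each in 1..10.
#' @param method `"mean"` or `"median"`.
#' @return Aggregated score in \[1, 10\].
#' @export
aggregate_observers <- function(scores, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(scores) == 0L) {
    abort("Need at least one observer score.", class = "pigait_error_parameter")
  }
  if (any(!is.finite(scores)) || any(scores < 1 | scores > 10) ||
      any(scores != round(scores))) {
    abort("Observer scores must be integers in 1..10.",
          class = "pigait_error_validation")
  }
  if (method == "mean") mean(scores) else stats::median(scores)
}

#' Per-animal PTIBS assessments from an observer-score table
#'
#' @param scores_tbl Tibble/data frame with columns `animal`, `group`,
#'   `session`, `observer`, `score`.
#' @param method Aggregation rule, see [aggregate_observers()].
#' @param rubric Rubric tibble (for category reporting).
#' @return A tibble with one row per animal x session: aggregated `score`,
#'   `n_observers`, and `category` (the common category when all observers
#'   agree, otherwise `"mixed"`).
#' @export
ptibs_assess <- function(scores_tbl, method = c("mean", "median"),
                         rubric = ptibs_rubric()) {
  method <- match.arg(method)
  cat_of <- function(lv) rubric$category[match(lv, rubric$level)]
  scores_tbl |>
    dplyr::group_by(.data$animal, .data$group, .data$session) |>
    dplyr::summarise(
      # category must be derived from the raw observer scores, so compute it
      # before `score` is rebound to the aggregate within this summarise()
      category = {
        cats <- unique(cat_of(.data$score))
        if (length(cats) == 1L) cats else "mixed"
      },
      n_observers = dplyr::n(),
      score = aggregate_observers(.data$score, method = method),
      .groups = "drop"
    ) |>
    dplyr::select("animal", "group", "session", "score", "n_observers",
                  "category")
}

#' Group-level PTIBS summary
#'
#' Mean +/- SEM of aggregated scores per group and session (sample SD, n-1
#' denominator; a single animal is reported with SEM 0 and flagged).
#'
#' @param assessments Tibble from [ptibs_assess()] (columns `animal`,
#'   `group`, `session`, `score`).
#' @return Tibble: `group`, `session`, `n`, `mean_score`, `sem_score`,
#'   `single_animal`.
#' @export
ptibs_group_summary <- function(assessments) {
  if (nrow(assessments) == 0L) {
    abort("No assessments to summarise.", class = "pigait_error_parameter")
  }
  assessments |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$score),
      sem_score = sem(.data$score),
      single_animal = dplyr::n() == 1L,
      .groups = "drop"
    )
}

#' PTIBS change from Baseline
#'
#' Per-animal change is the session score minus the animal's Baseline score;
#' the group change is the mean +/- SEM of per-animal changes.
#'
#' @param assessments Tibble from [ptibs_assess()] including Baseline rows
#'   for every animal.
#' @return Tibble: `group`, `session`, `n`, `mean_change`, `sem_change`.
#' @export
ptibs_change_from_baseline <- function(assessments) {
  base <- assessments |>
    dplyr::filter(.data$session == "Baseline") |>
    dplyr::select("animal", baseline_score = "score")
  miss <- setdiff(unique(assessments$animal), base$animal)
  if (length(miss) > 0L) {
    abort(paste0("Missing Baseline assessment for: ",
                 paste(miss, collapse = ", ")),
          class = "pigait_error_data")
  }
  assessments |>
    dplyr::filter(.data$session != "Baseline") |>
    dplyr::inner_join(base, by = "animal") |>
    dplyr::mutate(change = .data$score - .data$baseline_score) |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_change = mean(.data$change),
      sem_change = sem(.data$change),
      .groups = "drop"
    )
}
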