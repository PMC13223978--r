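# one small study shared by the report tests (built once per test run)
local_study <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$dir)) {
      cache$dir <- file.path(tempdir(), "pigait-report-study")
      generate_study(study_design(activity_minutes = 0.1, gait_seconds = 20),
                     cache$dir, seed = 17)
    }
    cache$dir
  }
})

test_that("study configuration round-trips through YAML losslessly", {
  cfg <- study_config("some/dir", out_dir = "out",
                      thresholds = activity_thresholds(4, 60),
                      gait = gait_config(block_seconds = 4,
                                         walk_band = c(2, 5),
                                         cycles_per_session = 8),
                      ptibs_method = "median", seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, f)
  back <- read_study_config(f)
  expect_equal(pigait:::config_as_list(back), pigait:::config_as_list(cfg))
})

test_that("run_study assembles every section and isolates failures", {
  dir <- local_study()
  rep <- run_study(study_config(dir, seed = 17))
  # activity: all 4 animals x 3 sessions x 2 placements
  expect_equal(nrow(rep$activity), 24L)
  expect_setequal(unique(rep$activity$session), c("Baseline", "Post2d", "Post14d"))
  # no hindlimb cycles at Post2d: gait rows only for Baseline / Post14d
  expect_false("Post2d" %in% rep$gait_metrics$session)
  expect_true(all(c("Baseline", "Post14d") %in% rep$gait_metrics$session))
  # the skipped sessions are surfaced in the log, not dropped silently
  expect_true(any(grepl("not analysable", rep$log$message)))
  # PTIBS summaries present with the designed group trajectory
  expect_equal(
    rep$ptibs_groups$mean_score[rep$ptibs_groups$group == "DAMAGED" &
                                  rep$ptibs_groups$session == "Baseline"], 10)
  expect_lt(
    rep$ptibs_changes$mean_change[rep$ptibs_changes$group == "DAMAGED" &
                                    rep$ptibs_changes$session == "Post2d"], -8)
  # deltas only exist where Baseline metrics exist
  expect_true(all(rep$gait_deltas$session != "Baseline"))
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("a missing goniometer file degrades gracefully", {
  dir <- withr::local_tempdir()
  file.copy(list.files(local_study(), full.names = TRUE), dir)
  unlink(file.path(dir, "P1_Baseline_gait_goniometer.csv"))
  rep <- run_study(study_config(dir))
  expect_equal(nrow(rep$activity), 24L)  # activity untouched
  expect_false(any(rep$gait_metrics$animal == "P1" &
                     rep$gait_metrics$session == "Baseline"))
  expect_true(any(rep$log$stage == "gait" & rep$log$animal == "P1"))
})

test_that("figure exports have the documented shapes", {
  rep <- run_study(study_config(local_study()))
  figs <- export_figures_data(rep)
  bars <- figs$activity_stacked |>
    dplyr::group_by(animal, session, placement) |>
    dplyr::summarise(total = sum(pct_time), .groups = "drop")
  expect_equal(bars$total, rep(100, nrow(bars)), tolerance = 1e-9)
  curves <- figs$cycle_curves |>
    dplyr::count(animal, session, side)
  expect_equal(curves$n, rep(101L, nrow(curves)))
  expect_true(any(figs$ptibs_trajectories$kind == "group_mean"))
  expect_true(any(figs$ptibs_trajectories$kind == "animal"))
})

test_that("plot builders return ggplot objects", {
  rep <- run_study(study_config(local_study()))
  expect_s3_class(plot_activity_fractions(rep$activity), "ggplot")
  expect_s3_class(plot_recovery(rep$activity), "ggplot")
  expect_s3_class(plot_ptibs(rep$ptibs), "ggplot")
  expect_s3_class(plot_gait_cycle(rep$cycle_curves), "ggplot")
})
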