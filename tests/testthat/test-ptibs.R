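test_that("the rubric has 10 levels partitioned into the three categories", {
  rub <- ptibs_rubric()
  expect_equal(rub$level, 1:10)
  expect_equal(rub$category, rep(c("dragging", "stepping", "walking"),
                                 c(3, 3, 4)))
})

test_that("behaviour descriptors map to their levels", {
  expect_equal(score_level("no active hindlimb movements")$level, 1L)
  expect_equal(score_level("no active hindlimb movements")$category, "dragging")
  lv2 <- score_level("active hindlimb movements, rump and knees on ground")
  expect_equal(lv2$level, 2L)
  lv10 <- score_level("Normal ambulation, normal balance")
  expect_equal(lv10$level, 10L)
  expect_equal(lv10$category, "walking")
  err <- tryCatch(score_level("moonwalking"), error = identity)
  expect_s3_class(err, "pigait_error_lookup")
  expect_match(conditionMessage(err), "normal ambulation")
})

test_that("observer aggregation is the mean (or median) of valid scores", {
  expect_equal(aggregate_observers(c(3L, 4L, 4L)), 11 / 3, tolerance = 1e-9)
  expect_equal(aggregate_observers(5L), 5)
  expect_equal(aggregate_observers(c(1L, 10L)), 5.5)
  expect_equal(aggregate_observers(c(2L, 5L, 9L), method = "median"), 5)
  expect_error(aggregate_observers(integer()), class = "pigait_error_parameter")
  expect_error(aggregate_observers(c(0L, 5L)), class = "pigait_error_validation")
  expect_error(aggregate_observers(c(3L, 11L)), class = "pigait_error_validation")
})

test_that("aggregated scores are bounded by the observer extremes", {
  set.seed(3)
  for (rep in 1:20) {
    s <- sample(1:10, sample(1:5, 1), replace = TRUE)
    for (m in c("mean", "median")) {
      a <- aggregate_observers(s, method = m)
      expect_gte(a, min(s)); expect_lte(a, max(s))
    }
  }
})

test_that("category is reported only under full observer agreement", {
  tbl <- tibble::tibble(
    animal = c("A", "A", "A", "B", "B", "B"),
    group = "DAMAGED", session = "Post14d",
    observer = rep(c("O1", "O2", "O3"), 2),
    score = c(4L, 5L, 6L,   3L, 4L, 4L))
  out <- ptibs_assess(tbl)
  expect_equal(out$category[out$animal == "A"], "stepping")
  expect_equal(out$category[out$animal == "B"], "mixed")
})

test_that("group summaries report mean and n-1 SEM", {
  tbl <- tibble::tibble(animal = c("A", "B", "C"), group = "DAMAGED",
                        session = "Post14d", score = c(3, 3.5, 4))
  grp <- ptibs_group_summary(tbl)
  expect_equal(grp$mean_score, 3.5)
  expect_equal(grp$sem_score, sd(c(3, 3.5, 4)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(grp$sem_score, 3), 0.289)
  one <- ptibs_group_summary(tbl[1, ])
  expect_equal(one$sem_score, 0)
  expect_true(one$single_animal)
})

test_that("change from Baseline averages per-animal deltas", {
  assess <- tibble::tibble(
    animal = rep(c("A", "B", "C"), each = 2),
    group = "DAMAGED",
    session = rep(c("Baseline", "Post14d"), 3),
    score = c(10, 3,   10, 3.5,   10, 4))
  ch <- ptibs_change_from_baseline(assess)
  expect_equal(ch$mean_change, -6.5)
  expect_equal(ch$sem_change, sd(c(-7, -6.5, -6)) / sqrt(3), tolerance = 1e-12)
  # antisymmetry: swapping the roles of the two sessions negates the change
  swapped <- dplyr::mutate(assess, session = dplyr::recode(
    session, Baseline = "Post14d", Post14d = "Baseline"))
  expect_equal(ptibs_change_from_baseline(swapped)$mean_change, 6.5)
  expect_error(ptibs_change_from_baseline(assess[assess$animal != "A" |
                                                   assess$session != "Baseline", ]),
               class = "pigait_error_data")
})
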