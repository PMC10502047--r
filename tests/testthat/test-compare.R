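tiny_scored <- function() {
  # hand-built scored cohort: 5 eye-exams across 2 subjects
  base <- tibble::tibble(
    subject_id = c("P1", "P1", "P1", "P2", "P2"),
    eye = c("OD", "OD", "OS", "OD", "OD"),
    birth_date = as.Date("2021-01-01"),
    exam_date = as.Date("2021-03-01") + c(0, 14, 0, 0, 14),
    ega_weeks = 27, pma_weeks = c(35.4, 37.4, 35.4, 35.4, 37.4),
    birth_weight_g = 1000, exam_weight_g = 1500,
    treated = c(FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  grading <- eye_grading(
    zone = c("II", "II", "PII", "II", "II"),
    stage = c("2", "3", "1", "1", "1"),
    plus = c("NONE", "PLUS", "NONE", "NONE", "PRE")
  )
  score_cohort(dplyr::bind_cols(base, grading))
}

test_that("score-return rates count numeric scores over graded eye-exams", {
  scored <- tiny_scored()
  tele <- score_return_rate(scored, "TELEROP_SS")
  mrop <- score_return_rate(scored, "MROP_ACTS")
  expect_equal(tele$overall, 1)
  # PII and PRE exams are unmappable: 3 of 5 return
  expect_equal(mrop$overall, 0.6)
  expect_equal(mrop$by_eye$rate[mrop$by_eye$eye == "OS"], 0)
  empty <- score_return_rate(tiny_scored()[0, ], "TELEROP_SS")
  expect_true(is.na(empty$overall))
})

test_that("treatment-warranted accuracy follows the identification rule", {
  scored <- tiny_scored()
  tele <- tw_accuracy(scored, "TELEROP_SS")
  # one treated eye (P1 OD), TW at the treatment exam (II/3/PLUS = 70)
  expect_equal(tele$overall, 1)
  mrop <- tw_accuracy(scored, "MROP_ACTS")
  # II/3/PLUS maps to a severe entry: identified under the label rule
  expect_equal(mrop$overall, 1)
  # threshold rule set impossibly high: miss, with a reason
  mrop25 <- tw_accuracy(scored, "MROP_ACTS", rule = "threshold",
                        threshold = 23L)
  expect_equal(mrop25$overall, 0)
  expect_equal(mrop25$cases$miss_reason, "BELOW_RULE")

  none <- tw_accuracy(scored[!scored$treated, ], "TELEROP_SS")
  expect_true(is.na(none$overall))
})

test_that("accuracy counts constructed fractions and conserves cases", {
  # 3 treated eyes; only 2 are flagged at or before treatment
  grading <- eye_grading(
    zone = c("I", "II", "PII"),
    stage = c("3", "2", "3"),
    plus = c("PLUS", "PLUS", "NONE")
  )
  scored <- score_cohort(dplyr::bind_cols(
    tibble::tibble(
      subject_id = c("Q1", "Q2", "Q3"), eye = "OD",
      birth_date = as.Date("2021-01-01"),
      exam_date = as.Date("2021-03-10"),
      ega_weeks = 26, pma_weeks = 35.7, birth_weight_g = 900,
      exam_weight_g = 1400, treated = TRUE
    ), grading))
  acc <- tw_accuracy(scored, "TELEROP_SS")
  expect_equal(acc$overall, 2 / 3, tolerance = 1e-12)
  expect_equal(sum(acc$by_eye$cases), nrow(acc$cases))
  # post-treatment exams are excluded from identification
  later <- scored
  later$treated <- FALSE
  later$exam_date <- later$exam_date + 21
  both <- dplyr::bind_rows(scored, later)
  expect_equal(tw_accuracy(both, "TELEROP_SS")$overall, 2 / 3,
               tolerance = 1e-12)
})

test_that("rank correlation matches hand-checkable cases and excludes no-scores", {
  expect_equal(spearman_correlation(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(30, 20, 10))$rho, -1)
  res <- spearman_correlation(c(1, 2, NA, 4, 5), c(2, 1, 9, 8, NA))
  expect_equal(res$n_pairs, 3)
  expect_equal(res$n_excluded, 2)
  expect_true(is.na(spearman_correlation(c(1, 2), c(3, 4))$rho))
})

test_that("rank correlation agrees with the permutation oracle under ties", {
  set.seed(404)
  cases <- list(
    list(x = c(3, 1, 4, 1, 5), y = c(2, 7, 1, 8, 2)),
    list(x = c(2, 2, 2, 1, 5, 4), y = c(1, 3, 3, 2, 6, 6)),
    list(x = sample(1:4, 7, replace = TRUE),
         y = sample(1:5, 7, replace = TRUE))
  )
  for (cs in cases) {
    expect_equal(spearman_correlation(cs$x, cs$y)$rho,
                 spearman_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("mixed-model machinery fits, flags degenerate designs and selects", {
  set.seed(7)
  dat <- simulate_lmm_scores(n_subjects = 60, slope_sd = 0)
  dat$pma_weeks <- dat$pma_weeks
  res <- fit_longitudinal_models(dat, "TELEROP_SS")
  expect_equal(nrow(res$OD$table), 4)
  expect_true(res$OD$selected %in% res$OD$table$model)
  expect_lt(res$OD$fixef[["pma_c"]], 0)  # recovers the declining trend

  # one exam per subject: no candidate is identifiable, and the selection
  # machinery reports that instead of failing
  single <- dat[!duplicated(dat$subject_id), ]
  res1 <- fit_longitudinal_models(single, "TELEROP_SS")
  expect_true(is.na(res1$OD$selected))
  expect_true(all(!res1$OD$table$converged |
                    !is.na(res1$OD$table$message)))

  # two exams per subject: random-slope candidates are still unidentifiable
  # but the random-intercept model fits
  two <- simulate_lmm_scores(n_subjects = 50, slope_sd = 0, n_exams = 2)
  tab2 <- fit_longitudinal_models(two, "TELEROP_SS")$OD$table
  expect_true(tab2$converged[tab2$model == "intercept"])
  expect_false(any(tab2$converged[tab2$model %in%
                                    c("slope", "covariates", "quadratic")]))
})

test_that("strong slope heterogeneity favours the random-slope model", {
  set.seed(21)
  wins <- 0
  for (r in 1:5) {
    dat <- simulate_lmm_scores(n_subjects = 80, slope_sd = 5)
    tab <- fit_longitudinal_models(dat, "TELEROP_SS")$OD$table
    a <- tab$aic[tab$model == "intercept"]
    b <- tab$aic[tab$model == "slope"]
    if (!is.na(a) && !is.na(b) && b < a) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("reports aggregate every statistic and serialize to JSON", {
  sim <- simulate_cohort(sim_config(n_subjects = 40, seed = 13))
  rep <- build_report(sim$cohort, fit_models = FALSE)
  expect_equal(rep$n_subjects, 40)
  expect_equal(rep$n_eye_scorings, nrow(sim$cohort))
  expect_equal(rep$return_rate$telerop$overall, 1)
  expect_true(rep$tw_accuracy$telerop$overall == 1 ||
                is.na(rep$tw_accuracy$telerop$overall))
  expect_gte(rep$tw_accuracy$telerop$overall,
             rep$tw_accuracy$mrop$overall)
  expect_true(abs(rep$spearman$pooled$rho) <= 1)
  # per-eye case counts sum to the overall case count
  expect_equal(sum(rep$tw_accuracy$telerop$by_eye$cases),
               nrow(rep$tw_accuracy$telerop$cases))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_subjects, 40)
  expect_length(utils::capture.output(summarise_accuracy(rep)), 5)

  untreated <- sim$cohort
  untreated$treated <- FALSE
  rep2 <- build_report(untreated, fit_models = FALSE)
  expect_true(is.na(rep2$tw_accuracy$telerop$overall))
  expect_match(rep2$tw_accuracy$telerop$reason, "no treated eyes")
})
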