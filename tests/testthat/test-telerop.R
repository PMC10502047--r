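test_that("the scorer reproduces every published severity-table row", {
  ref <- severity_reference()
  res <- score_telerop(eye_grading(zone = ref$zone, stage = ref$stage,
                                   plus = ref$plus, arop = ref$arop))
  expect_equal(res$score, ref$score)
  expect_equal(res$band, ref$band)

  # any-zone rows really are zone-independent
  any_rows <- ref[ref$any_zone, ]
  for (z in c("I", "PII", "II", "III")) {
    res_z <- score_telerop(eye_grading(z, any_rows$stage, any_rows$plus))
    expect_equal(res_z$score, any_rows$score)
  }
})

test_that("severity bands are the printed closed integer intervals", {
  expect_equal(severity_band(c(0, 25)), c("LOW", "LOW"))
  expect_equal(severity_band(c(26, 39)), c("MODERATE", "MODERATE"))
  expect_equal(severity_band(c(40, 54)), c("HIGH", "HIGH"))
  expect_equal(severity_band(c(55, 85)),
               rep("TREATMENT_WARRANTED", 2))
  expect_equal(severity_band(c(86, 100)), c("ADVERSE", "ADVERSE"))
  expect_error(severity_band(101), "range")
  expect_error(severity_band(-1), "range")
  # total and non-overlapping over the full score range
  bands <- severity_band(0:100)
  expect_false(anyNA(bands))
  expect_equal(rle(bands)$values,
               c("LOW", "MODERATE", "HIGH", "TREATMENT_WARRANTED",
                 "ADVERSE"))
})

test_that("scorer agrees with the additive/override oracle on every combination", {
  uni <- grading_universe()
  res <- score_telerop(eye_grading(zone = uni$zone, stage = uni$stage,
                                   plus = uni$plus,
                                   regression = uni$regression,
                                   arop = uni$arop))
  expected <- vapply(seq_len(nrow(uni)), function(i) {
    telerop_oracle(uni$zone[i], uni$stage[i], uni$plus[i],
                   uni$regression[i], uni$arop[i])
  }, numeric(1))
  expect_equal(as.numeric(res$score), expected)

  # range law: additive scores 15-85, adverse 86-100, nothing in between
  adverse <- uni$stage %in% c("4A", "4B", "5A", "5B", "5C")
  expect_true(all(res$score[adverse] >= 86 & res$score[adverse] <= 100))
  other <- !adverse & !is.na(res$score)
  expect_true(all(res$score[other] >= 15 & res$score[other] <= 85))
  expect_equal(res$band, severity_band(res$score))
  expect_equal(res$tw_flag[!is.na(res$score)],
               res$score[!is.na(res$score)] >= 55)
})

test_that("zone III and missing fields yield typed no-scores", {
  res <- score_telerop(eye_grading("III", "2", "PLUS"))
  expect_true(is.na(res$score))
  expect_equal(res$no_score_reason, "ZONE_III_UNSUPPORTED")

  res <- score_telerop(eye_grading(NA, "2", "PLUS"))
  expect_equal(res$no_score_reason, "MISSING_FIELDS")
  res <- score_telerop(eye_grading("II", NA, "PLUS"))
  expect_equal(res$no_score_reason, "MISSING_FIELDS")

  # a detachment stage needs no zone or plus; regression substitutes for
  # a missing stage
  expect_equal(score_telerop(eye_grading(NA, "5C", NA))$score, 100L)
  expect_equal(score_telerop(eye_grading("II", NA, "NONE",
                                         regression = "REGRESS"))$score, 25L)

  expect_error(score_telerop(eye_grading("II", "5A", "NONE",
                                         regression = "REGRESS")),
               "invalid gradings")
})

test_that("reactivation variants score like their base categories", {
  base <- score_telerop(eye_grading("PII", "2", "PRE",
                                    regression = "REGRESS-VEGFI"))
  react <- score_telerop(eye_grading("PII", "2", "PRE",
                                     regression = "REGRESS-VEGFI",
                                     reactivation = TRUE))
  expect_equal(react$score, base$score)
})

test_that("increasing any single factor never decreases the additive score", {
  zones <- c("II", "PII", "I")
  stages <- c("0", "1", "2", "3")
  pluses <- c("NONE", "PRE", "PLUS")
  grid <- expand.grid(z = seq_along(zones), s = seq_along(stages),
                      p = seq_along(pluses))
  score_of <- function(z, s, p) {
    score_telerop(eye_grading(zones[z], stages[s], pluses[p]))$score
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s0 <- score_of(g$z, g$s, g$p)
    if (g$z < 3) expect_gte(score_of(g$z + 1, g$s, g$p), s0)
    if (g$s < 4) expect_gte(score_of(g$z, g$s + 1, g$p), s0)
    if (g$p < 3) expect_gte(score_of(g$z, g$s, g$p + 1), s0)
  }
})

test_that("the six treatment indications all land in the treatment band", {
  ind <- treatment_indication_scores()
  expect_equal(nrow(ind), 6)
  expect_true(all(ind$score >= 55 & ind$score <= 85))
  expect_equal(min(ind$score), 55L)
  expect_equal(ind$score[ind$indication == "Zone I, any stage, plus"], 60L)
  expect_equal(ind$score[ind$indication == "Zone I, stage 3, no plus"], 55L)
})

test_that("every grading with Zone I, stage 3 and plus scores exactly 85", {
  for (reg in c("NONE", "REGRESS")) {
    g <- eye_grading("I", "3", "PLUS", regression = reg)
    res <- score_telerop(g)
    if (reg == "NONE") {
      expect_equal(res$score, 85L)
      expect_true(res$tw_flag)
    } else {
      # regression replaces the stage points; the eye is no longer an
      # active Zone I / stage 3 / plus configuration
      expect_equal(res$score, 70L)
    }
  }
})

test_that("tempo orders consecutive scores", {
  expect_equal(tempo(60, 45), "BETTER")
  expect_equal(tempo(45, 45), "SAME")
  expect_equal(tempo(45, 60), "WORSE")
  expect_equal(tempo(45, NA), "UNDEFINED")
  expect_equal(tempo(NA, 45), "UNDEFINED")
  expect_equal(tempo(c(60, 45, NA), c(45, 45, 45)),
               c("BETTER", "SAME", "UNDEFINED"))
})
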