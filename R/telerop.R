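#' Load the TeleROP-SS points allocation
#'
#' The telemedicine ROP severity score is additive over independently
#' weighted ICROP elements: Zone I / Posterior Zone II / Zone II earn
#' 30 / 20 / 15 points, stages 0-3 earn 0 / 3 / 10 / 25, regression of any
#' kind replaces the stage points with 10, and plus disease earns 0 / 5 / 30
#' for none / Pre-Plus / Plus. Aggressive ROP overrides the sum at 85, and
#' detachment stages 4A-5C map onto the reserved adverse-outcome band
#' 86-100. The allocation ships as a versioned plain-text file so future
#' ICROP amendments are data edits, not code edits.
#'
#' @param path Optional path to an alternative points file with columns
#'   `category`, `token`, `points`.
#' @return A list with elements `zone`, `stage`, `regression`, `plus`
#'   (named numeric vectors), `arop_score`, `adverse` (named numeric),
#'   `treatment_threshold` and `version` (the file's version comment line).
#' @export
telerop_points <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "telerop_points.csv", package = "ropscore")
  }
  version <- sub("^#\\s*", "", readLines(path, n = 1))
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(cat) {
    rows <- raw[raw$category == cat, ]
    setNames(as.numeric(rows$points), rows$token)
  }
  list(
    zone = pick("zone"),
    stage = pick("stage"),
    regression = pick("regression"),
    plus = pick("plus"),
    arop_score = unname(pick("override")["AROP"]),
    adverse = pick("adverse"),
    treatment_threshold = unname(pick("threshold")["TW"]),
    version = version
  )
}

no_score_reasons <- function() {
  c("NOT_APPLICABLE", "ZONE_III_UNSUPPORTED", "UNMAPPED_COMBINATION",
    "MISSING_FIELDS")
}

#' Map a severity score to its risk band
#'
#' Bands are closed integer intervals: low risk 0-25, moderate risk 26-39,
#' high risk 40-54, treatment warranted 55-85, adverse outcome 86-100.
#'
#' @param score Integer score(s) in 0-100.
#' @return Character vector of band labels (`"LOW"`, `"MODERATE"`, `"HIGH"`,
#'   `"TREATMENT_WARRANTED"`, `"ADVERSE"`); `NA` maps to `NA`.
#' @examples
#' severity_band(c(15, 26, 54, 85, 86))
#' @export
severity_band <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 100))) {
    stop("score out of range 0-100")
  }
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score <= 25 ~ "LOW",
    score <= 39 ~ "MODERATE",
    score <= 54 ~ "HIGH",
    score <= 85 ~ "TREATMENT_WARRANTED",
    TRUE ~ "ADVERSE"
  )
}

score_result <- function(system, score, reason, threshold) {
  tibble::tibble(
    system = system,
    score = as.integer(score),
    no_score_reason = reason,
    band = severity_band(score),
    tw_flag = ifelse(is.na(score), NA, score >= threshold)
  )
}

#' Score gradings with the telemedicine ROP severity score
#'
#' Resolution order per grading: a detachment stage (4A-5C) takes its fixed
#' adverse score (86, 89, 90, 95, 100) regardless of zone and plus; otherwise
#' aggressive ROP scores 85; otherwise the score is the additive sum of zone,
#' stage and plus points, where any recorded regression contributes 10 stage
#' points in place of the active-stage points and reactivation variants score
#' identically to their base categories. The additive branch requires zone in
#' \{I, PII, II\}: Zone III is outside the score's imaging envelope and
#' returns a typed no-score rather than a silent zero, as do gradings missing
#' a field the branch taken needs. Additive scores span 15 (Zone II,
#' incomplete vascularization, no plus) to 85 (Zone I, stage 3, plus).
#'
#' @param grading Grading tibble from [eye_grading()] (any number of rows).
#'   Must pass [validate_grading()] with no errors.
#' @param points Points allocation from [telerop_points()].
#' @return A tibble with one row per grading: `system` (`"TELEROP_SS"`),
#'   `score` (integer, `NA` when no score), `no_score_reason`, `band`,
#'   `tw_flag` (score at or above the treatment threshold of 55).
#' @examples
#' score_telerop(eye_grading("I", "3", "PLUS"))     # 85, treatment warranted
#' score_telerop(eye_grading("II", "0", "NONE"))    # 15, the scale floor
#' @export
score_telerop <- function(grading, points = telerop_points()) {
  findings <- validate_grading(grading)
  errs <- findings[findings$severity == "error", ]
  if (nrow(errs) > 0) {
    stop("invalid gradings (rows ", paste(unique(errs$row), collapse = ", "),
         "): ", errs$message[1])
  }
  n <- nrow(grading)
  score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  adverse <- !is.na(grading$stage) & grading$stage %in% names(points$adverse)
  score[adverse] <- points$adverse[grading$stage[adverse]]

  arop <- !adverse & !is.na(grading$arop) & grading$arop
  score[arop] <- points$arop_score

  additive <- !adverse & !arop
  zone3 <- additive & !is.na(grading$zone) & grading$zone == "III"
  reason[zone3] <- "ZONE_III_UNSUPPORTED"
  additive <- additive & !zone3

  regressed <- !is.na(grading$regression) & grading$regression != "NONE"
  # stage may be omitted for a regressed eye: regression supplies its points
  missing <- additive & (is.na(grading$zone) | is.na(grading$plus) |
                           (is.na(grading$stage) & !regressed))
  reason[missing] <- "MISSING_FIELDS"
  additive <- additive & !missing

  if (any(additive)) {
    idx <- which(additive)
    stage_pts <- ifelse(regressed[idx],
                        points$regression[grading$regression[idx]],
                        points$stage[grading$stage[idx]])
    score[idx] <- points$zone[grading$zone[idx]] + stage_pts +
      points$plus[grading$plus[idx]]
  }
  score_result("TELEROP_SS", score, reason, points$treatment_threshold)
}

#' Enumerate the treatment indications and their minimal scores
#'
#' The six accepted treatment indications, each instantiated with the
#' grading(s) that minimally qualify, scored with the severity score. The
#' scale is weighted so that every indication lands in the
#' treatment-warranted band (55-85); the minimum over all six is the
#' treatment threshold itself, 55.
#'
#' @param points Points allocation from [telerop_points()].
#' @return A tibble with columns `indication`, `zone`, `stage`, `plus`,
#'   `arop`, `score`; one row per minimal qualifying grading.
#' @export
treatment_indication_scores <- function(points = telerop_points()) {
  # minimal qualifying grading(s) per indication: the least-severe ICROP
  # combination that still meets the printed wording
  spec <- list(
    list("Zone I, any stage, plus", "I", "0", "PLUS", FALSE),
    list("Zone I or II, stage 2 or 3, plus", "II", "2", "PLUS", FALSE),
    list("AROP (Zone I / Posterior Zone II / Zone II with plus)",
         "II", "1", "PLUS", TRUE),
    list("Zone I or II, stage 3, 5 continuous clock hours, plus, 4 quadrants",
         "II", "3", "PLUS", FALSE),
    list("Zone I or II, stage 3, 8 interrupted clock hours, plus, 4 quadrants",
         "II", "3", "PLUS", FALSE),
    list("Zone I, stage 3, no plus", "I", "3", "NONE", FALSE)
  )
  rows <- lapply(spec, function(s) {
    g <- eye_grading(zone = s[[2]], stage = s[[3]], plus = s[[4]],
                     arop = s[[5]])
    res <- score_telerop(g, points)
    tibble::tibble(indication = s[[1]], zone = s[[2]], stage = s[[3]],
                   plus = s[[4]], arop = s[[5]], score = res$score)
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(out$score >= points$treatment_threshold))
  out
}

#' Between-exam direction of change (tempo)
#'
#' Compares consecutive scores of the same eye: a fall is improvement
#' (`"BETTER"`), no change is `"SAME"`, a rise is `"WORSE"`. When either
#' exam returned no score the direction is `"UNDEFINED"`.
#'
#' @param previous,current Integer scores (or `NA` for no score), recycled
#'   to a common length.
#' @return Character vector of `"BETTER"`, `"SAME"`, `"WORSE"`,
#'   `"UNDEFINED"`.
#' @examples
#' tempo(60, 45)
#' @export
tempo <- function(previous, current) {
  dplyr::case_when(
    is.na(previous) | is.na(current) ~ "UNDEFINED",
    current < previous ~ "BETTER",
    current > previous ~ "WORSE",
    TRUE ~ "SAME"
  )
}
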