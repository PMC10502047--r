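#' Controlled vocabularies for ICROP eye gradings
#'
#' Token sets used throughout the package for per-eye ICROP gradings, in the
#' short forms used on grading sheets: zones `I` (Zone I), `PII` (Posterior
#' Zone II), `II`, `III`; stages `0` (incomplete vascularization without ROP)
#' through `3`, detachment stages `4A`/`4B` (partial) and `5A`/`5B`/`5C`
#' (total); plus `NONE`, `PRE` (Pre-Plus) and `PLUS`; regression `NONE`,
#' `REGRESS` (spontaneous), `REGRESS-VEGFI` (after anti-VEGF injection) and
#' `REGRESS-LASER` (after laser retinopexy).
#'
#' @return A character vector of valid tokens.
#' @name rop_vocab
NULL

#' @rdname rop_vocab
#' @export
rop_zones <- function() c("I", "PII", "II", "III")

#' @rdname rop_vocab
#' @export
rop_stages <- function() c("0", "1", "2", "3", "4A", "4B", "5A", "5B", "5C")

#' @rdname rop_vocab
#' @export
rop_plus_states <- function() c("NONE", "PRE", "PLUS")

#' @rdname rop_vocab
#' @export
rop_regression_states <- function() {
  c("NONE", "REGRESS", "REGRESS-VEGFI", "REGRESS-LASER")
}

# detachment stages excluded by regression and by AROP at scoring time
detached_stages <- function() c("4A", "4B", "5A", "5B", "5C")

#' Construct a table of per-eye ICROP gradings
#'
#' Builds a tibble with one row per grading, filling optional fields with
#' their neutral values (`regression = "NONE"`, `reactivation = FALSE`,
#' `arop = FALSE`) and leaving truly unknown fields `NA`. Vectorised: all
#' arguments recycle to a common length.
#'
#' @param zone Zone token (`"I"`, `"PII"`, `"II"`, `"III"`) or `NA`.
#' @param stage Stage token (`"0"`–`"3"`, `"4A"`–`"5C"`) or `NA`.
#'   Numeric stages are accepted and converted.
#' @param plus Plus-disease token (`"NONE"`, `"PRE"`, `"PLUS"`) or `NA`.
#' @param regression Regression token; `"NONE"` when disease is active.
#' @param reactivation Logical; grading describes reactivated disease.
#' @param arop Logical; aggressive ROP.
#' @param extent_hours Clock hours of stage (0–12); recorded, never scored.
#' @param plus_quadrants Quadrants of plus (0–4); recorded, never scored.
#'
#' @return A tibble with the eight grading columns.
#' @examples
#' eye_grading(zone = "I", stage = "3", plus = "PLUS")
#' @export
eye_grading <- function(zone = NA_character_, stage = NA_character_,
                        plus = NA_character_, regression = "NONE",
                        reactivation = FALSE, arop = FALSE,
                        extent_hours = NA_integer_,
                        plus_quadrants = NA_integer_) {
  tibble::tibble(
    zone = as.character(zone),
    stage = as.character(stage),
    plus = as.character(plus),
    regression = as.character(regression),
    reactivation = as.logical(reactivation),
    arop = as.logical(arop),
    extent_hours = as.integer(extent_hours),
    plus_quadrants = as.integer(plus_quadrants)
  )
}

grading_columns <- function() {
  c("zone", "stage", "plus", "regression", "reactivation", "arop",
    "extent_hours", "plus_quadrants")
}

new_finding <- function(row, code, severity, message) {
  tibble::tibble(row = as.integer(row), code = code,
                 severity = severity, message = message)
}

empty_findings <- function() {
  tibble::tibble(row = integer(), code = character(),
                 severity = character(), message = character())
}

#' Validate ICROP gradings
#'
#' Checks token membership and the cross-field ICROP consistency rules:
#' regressed disease cannot carry a detachment stage (regression describes
#' involuting, attached retina), aggressive ROP cannot carry a detachment
#' stage at scoring time (the detachment outcome supersedes it), and
#' reactivation recorded without any regression history is flagged as a
#' warning only, since a standalone cross-sectional record cannot prove the
#' history either way. Findings are returned, never raised, so callers can
#' decide whether warnings block scoring.
#'
#' @param grading A grading tibble as built by [eye_grading()] (one or more
#'   rows).
#' @return A tibble of findings with columns `row`, `code`,
#'   `severity` (`"error"` or `"warning"`) and `message`; zero rows when the
#'   gradings are valid.
#' @examples
#' validate_grading(eye_grading("I", "3", "PLUS"))           # no findings
#' validate_grading(eye_grading("II", "5A", regression = "REGRESS"))
#' @export
validate_grading <- function(grading) {
  stopifnot(is.data.frame(grading))
  missing_cols <- setdiff(grading_columns(), names(grading))
  if (length(missing_cols) > 0) {
    stop("grading is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  findings <- list(empty_findings())
  bad_token <- function(field, valid) {
    vals <- grading[[field]]
    bad <- which(!is.na(vals) & !(vals %in% valid))
    if (length(bad) == 0) return(empty_findings())
    new_finding(bad, paste0("bad_", field, "_token"), "error",
                sprintf("invalid %s token '%s'", field, vals[bad]))
  }
  findings <- c(findings, list(
    bad_token("zone", rop_zones()),
    bad_token("stage", rop_stages()),
    bad_token("plus", rop_plus_states()),
    bad_token("regression", rop_regression_states())
  ))

  regressed <- !is.na(grading$regression) & grading$regression != "NONE"
  detached <- !is.na(grading$stage) & grading$stage %in% detached_stages()
  bad <- which(regressed & detached)
  if (length(bad) > 0) {
    findings <- c(findings, list(new_finding(
      bad, "regression_excludes_detachment", "error",
      "regressed disease cannot carry a detachment stage (4A-5C)"
    )))
  }
  bad <- which(!is.na(grading$arop) & grading$arop & detached)
  if (length(bad) > 0) {
    findings <- c(findings, list(new_finding(
      bad, "arop_excludes_detachment", "error",
      "AROP cannot be scored together with a detachment stage (4A-5C)"
    )))
  }
  react <- which(!is.na(grading$reactivation) & grading$reactivation &
                   !regressed)
  if (length(react) > 0) {
    findings <- c(findings, list(new_finding(
      react, "reactivation_without_regression_history", "warning",
      "reactivation recorded without regression on the same record; accepted as-is for standalone records"
    )))
  }
  for (field in c("extent_hours", "plus_quadrants")) {
    hi <- if (field == "extent_hours") 12L else 4L
    vals <- grading[[field]]
    bad <- which(!is.na(vals) & (vals < 0L | vals > hi))
    if (length(bad) > 0) {
      findings <- c(findings, list(new_finding(
        bad, paste0(field, "_out_of_range"), "error",
        sprintf("%s must lie in 0-%d", field, hi)
      )))
    }
  }
  out <- dplyr::bind_rows(findings)
  dplyr::arrange(out, .data$row, .data$code)
}

#' Derive postmenstrual age at exam
#'
#' PMA at exam is gestational age at birth plus elapsed calendar time:
#' `ega_weeks + (exam_date - birth_date) / 7`, reported to one decimal week,
#' the precision screening records use.
#'
#' @param ega_weeks Estimated gestational age at birth, decimal weeks (> 0).
#' @param birth_date,exam_date `Date` vectors; `exam_date` must not precede
#'   `birth_date`.
#' @return Decimal weeks, rounded to one decimal.
#' @examples
#' derive_pma(25, as.Date("2020-01-01"), as.Date("2020-02-12"))  # 31.0
#' @export
derive_pma <- function(ega_weeks, birth_date, exam_date) {
  birth_date <- as.Date(birth_date)
  exam_date <- as.Date(exam_date)
  if (any(!is.na(ega_weeks) & ega_weeks <= 0)) {
    stop("ega_weeks must be positive")
  }
  elapsed <- as.numeric(exam_date - birth_date)
  if (any(!is.na(elapsed) & elapsed < 0)) {
    stop("exam_date precedes birth_date")
  }
  round(ega_weeks + elapsed / 7, 1)
}
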