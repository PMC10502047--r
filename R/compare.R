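system_cols <- function(system) {
  system <- match.arg(system, c("TELEROP_SS", "MROP_ACTS"))
  if (system == "TELEROP_SS") {
    list(score = "telerop_score", flag = "telerop_tw")
  } else {
    list(score = "mrop_score", flag = "mrop_severe")
  }
}

#' Score-return rate of a scoring system
#'
#' The fraction of graded eye-exams for which the system returns a numeric
#' score, overall and per eye. The telemedicine severity score returns a
#' score for every grading within its imaging envelope (no Zone III), while
#' the activity-scale comparator cannot map Posterior Zone II, Pre-Plus,
#' regression or reactivation gradings.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param system `"TELEROP_SS"` or `"MROP_ACTS"`.
#' @return A list with `overall` (fraction, `NA` on an empty cohort),
#'   `by_eye` (tibble: `eye`, `n`, `returned`, `rate`) and `n` (eye-exams).
#' @export
score_return_rate <- function(scored, system = c("TELEROP_SS", "MROP_ACTS")) {
  cols <- system_cols(match.arg(system))
  if (nrow(scored) == 0) {
    return(list(overall = NA_real_,
                by_eye = tibble::tibble(eye = character(), n = integer(),
                                        returned = integer(), rate = double()),
                n = 0L))
  }
  by_eye <- scored |>
    dplyr::group_by(.data$eye) |>
    dplyr::summarise(n = dplyr::n(),
                     returned = sum(!is.na(.data[[cols$score]])),
                     rate = .data$returned / .data$n, .groups = "drop")
  list(overall = sum(by_eye$returned) / sum(by_eye$n), by_eye = by_eye,
       n = nrow(scored))
}

#' Treatment-warranted identification accuracy
#'
#' A case is one treated eye. A system identifies the case when at least one
#' exam at or before the treatment date carries the system's
#' treatment-warranted flag: for the severity score, a score at or above the
#' treatment threshold; for the activity scale, either a returned entry
#' labelled severe (`rule = "severe-label"`, the default) or a returned
#' value at or above `threshold` (`rule = "threshold"`). Exams after the
#' treatment date are ignored — post-treatment regression would deflate the
#' measure spuriously. An exam where the system returns no score can never
#' identify a case.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param system `"TELEROP_SS"` or `"MROP_ACTS"`.
#' @param rule Identification rule for the activity scale (ignored for the
#'   severity score).
#' @param threshold Value cut-off for `rule = "threshold"`.
#' @return A list with `overall` (identified / cases, `NA` when the cohort
#'   has no treated eyes), `by_eye` (per-eye tibble), and `cases` (one row
#'   per treated eye: identification flag and, for misses, the reason —
#'   `"NO_SCORE_RETURNED"` when every qualifying exam was unmappable,
#'   `"BELOW_RULE"` otherwise).
#' @export
tw_accuracy <- function(scored, system = c("TELEROP_SS", "MROP_ACTS"),
                        rule = c("severe-label", "threshold"),
                        threshold = 10L) {
  system <- match.arg(system)
  rule <- match.arg(rule)
  cols <- system_cols(system)
  treated <- scored[!is.na(scored$treated) & scored$treated, ]
  if (nrow(treated) == 0) {
    return(list(overall = NA_real_, by_eye = NULL, cases = NULL,
                reason = "no treated eyes in cohort"))
  }
  treat_dates <- treated |>
    dplyr::group_by(.data$subject_id, .data$eye) |>
    dplyr::summarise(treat_date = min(.data$exam_date), .groups = "drop")
  flag_of <- function(df) {
    if (system == "TELEROP_SS" || rule == "severe-label") {
      !is.na(df[[cols$flag]]) & df[[cols$flag]]
    } else {
      !is.na(df[[cols$score]]) & df[[cols$score]] >= threshold
    }
  }
  cases <- treat_dates |>
    dplyr::rowwise() |>
    dplyr::mutate(case = list({
      exams <- scored[scored$subject_id == .data$subject_id &
                        scored$eye == .data$eye &
                        scored$exam_date <= .data$treat_date, ]
      any_score <- any(!is.na(exams[[cols$score]]))
      tibble::tibble(
        identified = any(flag_of(exams)),
        miss_reason = dplyr::if_else(
          any(flag_of(exams)), NA_character_,
          dplyr::if_else(any_score, "BELOW_RULE", "NO_SCORE_RETURNED"))
      )
    })) |>
    dplyr::ungroup() |>
    tidyr_unnest_case()
  by_eye <- cases |>
    dplyr::group_by(.data$eye) |>
    dplyr::summarise(cases = dplyr::n(), identified = sum(.data$identified),
                     accuracy = .data$identified / .data$cases,
                     .groups = "drop")
  list(overall = sum(cases$identified) / nrow(cases), by_eye = by_eye,
       cases = cases)
}

# minimal unnest of the one-row `case` list column (avoids a tidyr dependency)
tidyr_unnest_case <- function(df) {
  inner <- dplyr::bind_rows(df$case)
  dplyr::bind_cols(df[setdiff(names(df), "case")], inner)
}

#' Spearman rank correlation between two score series
#'
#' Rank-based correlation with average (mid) ranks for ties. Pairs where
#' either score is missing (a typed no-score) are excluded and counted; with
#' fewer than three complete pairs the coefficient is undefined and `NA` is
#' returned.
#'
#' @param score_a,score_b Numeric score vectors of equal length.
#' @return A list with `rho`, `n_pairs` (complete pairs used) and
#'   `n_excluded`.
#' @examples
#' spearman_correlation(c(1, 2, 3), c(10, 20, 30))$rho  # 1
#' @export
spearman_correlation <- function(score_a, score_b) {
  stopifnot(length(score_a) == length(score_b))
  complete <- !is.na(score_a) & !is.na(score_b)
  n <- sum(complete)
  rho <- if (n >= 3) {
    cor(score_a[complete], score_b[complete], method = "spearman")
  } else {
    NA_real_
  }
  list(rho = rho, n_pairs = n, n_excluded = sum(!complete))
}

default_lmm_candidates <- function() {
  list(
    intercept = score ~ pma_c + (1 | subject_id),
    slope = score ~ pma_c + (pma_c | subject_id),
    covariates = score ~ pma_c + ega_weeks + birth_weight_g +
      (pma_c | subject_id),
    quadratic = score ~ pma_c + I(pma_c^2) + (pma_c | subject_id)
  )
}

#' Fit and select longitudinal mixed-effects trend models
#'
#' Repeated scores of the same eyes are not independent, so the score trend
#' over postmenstrual age is modelled per eye laterality with linear
#' mixed-effects models: subjects contribute random intercepts and,
#' in richer candidates, random PMA slopes. The default candidate set is
#' (a) fixed PMA trend with random subject intercepts, (b) a with random PMA
#' slopes, (c) b with gestational age and birth weight as fixed covariates,
#' (d) b with a quadratic PMA term. All candidates are fitted by maximum
#' likelihood (not REML) so their AIC values are comparable, and the
#' minimum-AIC candidate among those that converge is selected per eye.
#' PMA enters centred (`pma_c = pma_weeks - 36`).
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param system Which system's scores to model.
#' @param candidates Named list of `lme4::lmer` formulas over the columns
#'   `score`, `pma_c`, `ega_weeks`, `birth_weight_g`, `subject_id`.
#' @return A list per eye (`OD`, `OS`): `table` (tibble with `model`,
#'   `aic`, `converged`, `singular`, `message`), `selected` (name of the
#'   minimum-AIC converged candidate) and `fixef` (its fixed effects).
#' @export
fit_longitudinal_models <- function(scored,
                                    system = c("TELEROP_SS", "MROP_ACTS"),
                                    candidates = default_lmm_candidates()) {
  cols <- system_cols(match.arg(system))
  out <- list()
  for (e in c("OD", "OS")) {
    df <- scored[scored$eye == e & !is.na(scored[[cols$score]]) &
                   !is.na(scored$pma_weeks), ]
    dat <- tibble::tibble(
      score = as.numeric(df[[cols$score]]),
      pma_c = df$pma_weeks - 36,
      ega_weeks = df$ega_weeks,
      birth_weight_g = df$birth_weight_g,
      subject_id = df$subject_id
    )
    if (nrow(dat) < 3) {
      out[[e]] <- list(table = tibble::tibble(
        model = names(candidates), aic = NA_real_, converged = FALSE,
        singular = NA, message = "insufficient data"),
        selected = NA_character_, fixef = NULL)
      next
    }
    out[[e]] <- select_lmm(dat, candidates)
  }
  out
}

select_lmm <- function(dat, candidates) {
  rows <- lapply(names(candidates), function(nm) {
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(candidates[[nm]], data = dat, REML = FALSE),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble::tibble(model = nm, aic = NA_real_, converged = FALSE,
                            singular = NA, message = conditionMessage(fit),
                            fit = list(NULL)))
    }
    conv <- length(fit@optinfo$conv$lme4) == 0 ||
      is.null(fit@optinfo$conv$lme4$messages)
    tibble::tibble(model = nm, aic = AIC(fit), converged = conv,
                   singular = lme4::isSingular(fit),
                   message = NA_character_, fit = list(fit))
  })
  table <- dplyr::bind_rows(rows)
  ok <- which(table$converged & !is.na(table$aic))
  if (length(ok) == 0) {
    return(list(table = table[setdiff(names(table), "fit")],
                selected = NA_character_, fixef = NULL))
  }
  best <- ok[which.min(table$aic[ok])]
  list(table = table[setdiff(names(table), "fit")],
       selected = table$model[best],
       fixef = lme4::fixef(table$fit[[best]]))
}

#' Build a cohort-level comparison report
#'
#' Scores every eye-exam with both systems and assembles the comparison:
#' score-return rates, treatment-warranted identification accuracy (when the
#' cohort contains treated eyes), Spearman rank correlation per eye and
#' pooled over exams where both systems return a score, and mixed-model
#' trend selection (when requested). Serializable to JSON with
#' [write_report()].
#'
#' @param cohort A cohort tibble (scored or not; scoring columns are added
#'   when absent).
#' @param mrop_rule,mrop_threshold Identification rule for the activity
#'   scale, as in [tw_accuracy()].
#' @param fit_models Fit the longitudinal candidates (the slowest step;
#'   disable for quick coverage-only reports).
#' @return A `comparison_report` list with elements `n_subjects`, `n_exams`,
#'   `n_eye_scorings`, `return_rate`, `tw_accuracy`, `spearman`,
#'   `lme_results` and `tables` (versions of both bundled score tables).
#' @export
build_report <- function(cohort, mrop_rule = c("severe-label", "threshold"),
                         mrop_threshold = 10L, fit_models = TRUE) {
  mrop_rule <- match.arg(mrop_rule)
  points <- telerop_points()
  table <- mrop_table()
  scored <- if (all(scored_columns() %in% names(cohort))) {
    cohort
  } else {
    score_cohort(cohort, points, table)
  }
  spearman_by <- function(df) {
    spearman_correlation(df$telerop_score, df$mrop_score)
  }
  report <- list(
    n_subjects = dplyr::n_distinct(scored$subject_id),
    n_exams = dplyr::n_distinct(paste(scored$subject_id, scored$exam_date)),
    n_eye_scorings = nrow(scored),
    return_rate = list(
      telerop = score_return_rate(scored, "TELEROP_SS"),
      mrop = score_return_rate(scored, "MROP_ACTS")
    ),
    tw_accuracy = list(
      rule = mrop_rule,
      telerop = tw_accuracy(scored, "TELEROP_SS"),
      mrop = tw_accuracy(scored, "MROP_ACTS", rule = mrop_rule,
                         threshold = mrop_threshold)
    ),
    spearman = list(
      pooled = spearman_by(scored),
      OD = spearman_by(scored[scored$eye == "OD", ]),
      OS = spearman_by(scored[scored$eye == "OS", ])
    ),
    lme_results = if (fit_models) fit_longitudinal_models(scored) else NULL,
    tables = list(telerop_points = points$version,
                  mrop_table = "synthetic reconstruction v1.0")
  )
  structure(report, class = "comparison_report")
}

#' Write a comparison report to JSON
#'
#' @param report A `comparison_report` from [build_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  clean <- serialize_report(report)
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

serialize_report <- function(x) {
  if (inherits(x, "comparison_report")) x <- unclass(x)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, serialize_report))
  x
}

#' Plain-text accuracy summary
#'
#' A small fixed-width table of treatment-warranted identification accuracy
#' by system, overall and per eye.
#'
#' @param report A `comparison_report`.
#' @return A character vector of lines, invisibly; printed as a side effect.
#' @export
summarise_accuracy <- function(report) {
  acc <- report$tw_accuracy
  fmt <- function(x) ifelse(is.na(x), "  n/a", sprintf("%5.2f", x))
  get_eye <- function(sys, e) {
    be <- acc[[sys]]$by_eye
    if (is.null(be) || !e %in% be$eye) NA_real_ else be$accuracy[be$eye == e]
  }
  lines <- c(
    "TW-ROP identification accuracy",
    sprintf("%-10s %9s %11s", "", "mROP-ActS", "TeleROP-SS"),
    sprintf("%-10s %9s %11s", "Overall", fmt(acc$mrop$overall),
            fmt(acc$telerop$overall)),
    sprintf("%-10s %9s %11s", "Right eye", fmt(get_eye("mrop", "OD")),
            fmt(get_eye("telerop", "OD"))),
    sprintf("%-10s %9s %11s", "Left eye", fmt(get_eye("mrop", "OS")),
            fmt(get_eye("telerop", "OS")))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
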