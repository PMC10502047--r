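cohort_columns <- function() {
  c("subject_id", "eye", "birth_date", "exam_date", "ega_weeks", "pma_weeks",
    "birth_weight_g", "exam_weight_g", grading_columns(), "treated")
}

cohort_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    eye = readr::col_character(),
    birth_date = readr::col_date(),
    exam_date = readr::col_date(),
    ega_weeks = readr::col_double(),
    pma_weeks = readr::col_double(),
    birth_weight_g = readr::col_double(),
    exam_weight_g = readr::col_double(),
    zone = readr::col_character(),
    stage = readr::col_character(),
    plus = readr::col_character(),
    regression = readr::col_character(),
    reactivation = readr::col_logical(),
    arop = readr::col_logical(),
    extent_hours = readr::col_integer(),
    plus_quadrants = readr::col_integer(),
    treated = readr::col_logical(),
    .default = readr::col_guess()
  )
}

empty_cohort <- function() {
  g <- eye_grading()[0, ]
  tibble::tibble(
    subject_id = character(), eye = character(),
    birth_date = as.Date(character()), exam_date = as.Date(character()),
    ega_weeks = double(), pma_weeks = double(),
    birth_weight_g = double(), exam_weight_g = double()
  ) |>
    dplyr::bind_cols(g) |>
    dplyr::mutate(treated = logical())
}

#' Read a longitudinal exam cohort from CSV
#'
#' Two layouts are supported. `long`: one row per eye-exam with the canonical
#' columns (`subject_id`, `eye`, `birth_date`, `exam_date`, `ega_weeks`,
#' `pma_weeks`, `birth_weight_g`, `exam_weight_g`, the grading columns, and
#' `treated`). `wide`: one row per exam with per-eye grading columns suffixed
#' `_od` / `_os`, expanded to two records (an eye whose grading cells are all
#' blank contributes no record). Blank cells become `NA`, never silent
#' defaults. `pma_weeks` is derived from `ega_weeks` and the dates when
#' absent; when both are supplied they must agree within 0.05 weeks.
#'
#' @param path CSV file path.
#' @param layout `"long"` (default) or `"wide"`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's headers, e.g. `c(subject_id = "mrn_anon")`, so
#'   externally curated deposits can be ingested without code changes.
#' @return A cohort tibble sorted by (`subject_id`, `eye`, `exam_date`), with
#'   a `metadata` attribute (source path, layout, schema version).
#' @export
read_cohort <- function(path, layout = c("long", "wide"), col_map = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  header <- gsub('"', "", strsplit(readLines(path, n = 1), ",")[[1]])
  spec <- cohort_col_types()$cols
  present <- intersect(names(spec), header)
  types <- do.call(readr::cols,
                   c(spec[present], list(.default = readr::col_guess())))
  raw <- readr::read_csv(path, show_col_types = FALSE, col_types = types)
  if (!is.null(col_map)) {
    hit <- match(unname(col_map), names(raw))
    names(raw)[hit[!is.na(hit)]] <- names(col_map)[!is.na(hit)]
  }
  if (layout == "wide") {
    cohort <- widen_to_long(raw)
  } else {
    missing_cols <- setdiff(cohort_columns(), names(raw))
    for (m in missing_cols) raw[[m]] <- NA
    cohort <- raw[cohort_columns()]
  }
  if (nrow(cohort) == 0) {
    out <- empty_cohort()
    attr(out, "metadata") <- cohort_metadata(path, layout)
    return(out)
  }
  for (col in c("subject_id", "eye", "zone", "stage", "plus", "regression")) {
    cohort[[col]] <- as.character(cohort[[col]])
  }
  for (col in c("birth_date", "exam_date")) {
    cohort[[col]] <- as.Date(cohort[[col]])
  }
  for (col in c("ega_weeks", "pma_weeks", "birth_weight_g", "exam_weight_g")) {
    cohort[[col]] <- as.numeric(cohort[[col]])
  }
  cohort$treated <- as.logical(cohort$treated)
  cohort$reactivation <- as.logical(cohort$reactivation)
  cohort$arop <- as.logical(cohort$arop)
  cohort$extent_hours <- as.integer(cohort$extent_hours)
  cohort$plus_quadrants <- as.integer(cohort$plus_quadrants)

  findings <- validate_grading(cohort[grading_columns()])
  tok <- findings[findings$severity == "error" &
                    startsWith(findings$code, "bad_"), ]
  if (nrow(tok) > 0) {
    stop("unparseable grading tokens at row(s) ",
         paste(unique(tok$row), collapse = ", "), ": ", tok$message[1])
  }
  key <- paste(cohort$subject_id, cohort$eye, cohort$exam_date)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicate (subject, eye, exam date) records: ",
         paste(unique(dup), collapse = "; "))
  }
  derivable <- is.na(cohort$pma_weeks) & !is.na(cohort$ega_weeks) &
    !is.na(cohort$birth_date) & !is.na(cohort$exam_date)
  if (any(derivable)) {
    cohort$pma_weeks[derivable] <- derive_pma(
      cohort$ega_weeks[derivable], cohort$birth_date[derivable],
      cohort$exam_date[derivable])
  }
  both <- !is.na(cohort$pma_weeks) & !is.na(cohort$ega_weeks) &
    !is.na(cohort$birth_date) & !is.na(cohort$exam_date)
  if (any(both)) {
    expected <- derive_pma(cohort$ega_weeks[both], cohort$birth_date[both],
                           cohort$exam_date[both])
    off <- abs(cohort$pma_weeks[both] - expected) > 0.05 + 1e-9
    if (any(off)) {
      stop("pma_weeks inconsistent with ega_weeks and dates at row(s) ",
           paste(which(both)[off], collapse = ", "))
    }
  }
  out <- dplyr::arrange(cohort, .data$subject_id, .data$eye, .data$exam_date)
  attr(out, "metadata") <- cohort_metadata(path, layout)
  out
}

cohort_metadata <- function(source, layout) {
  list(source = source, layout = layout, schema_version = "1.0")
}

widen_to_long <- function(raw) {
  shared <- c("subject_id", "birth_date", "exam_date", "ega_weeks",
              "pma_weeks", "birth_weight_g", "exam_weight_g")
  per_eye <- c(grading_columns(), "treated")
  rows <- list(empty_cohort())
  for (eye in c("OD", "OS")) {
    suffix <- paste0("_", tolower(eye))
    cols <- paste0(per_eye, suffix)
    present <- cols %in% names(raw)
    if (!any(present)) next
    part <- raw[intersect(shared, names(raw))]
    for (m in setdiff(shared, names(raw))) part[[m]] <- NA
    part$eye <- eye
    for (k in seq_along(per_eye)) {
      part[[per_eye[k]]] <- if (present[k]) raw[[cols[k]]] else NA
    }
    for (tok in c("zone", "stage", "plus", "regression")) {
      part[[tok]] <- as.character(part[[tok]])
    }
    for (lg in c("reactivation", "arop", "treated")) {
      part[[lg]] <- as.logical(part[[lg]])
    }
    for (num in c("extent_hours", "plus_quadrants")) {
      part[[num]] <- as.integer(part[[num]])
    }
    graded <- rowSums(!is.na(part[c("zone", "stage", "plus")])) > 0
    rows <- c(rows, list(part[graded, c(shared[1], "eye", shared[-1],
                                        per_eye)]))
  }
  out <- dplyr::bind_rows(rows)
  out[cohort_columns()]
}

#' Write a cohort to the long CSV layout
#'
#' Inverse of [read_cohort()] for the long layout: UTF-8, comma-separated,
#' ISO-8601 dates, the grading tokens of the controlled vocabularies.
#' `read_cohort(write_cohort(x))` reproduces `x` field-by-field.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[cohort_columns()], path, na = "")
  invisible(path)
}

#' Score every eye-exam of a cohort with both systems
#'
#' Runs the telemedicine severity score and the activity-scale lookup on
#' every record and appends, per system, the score, no-score reason, band or
#' label, treatment-warranted / severe flag, and the tempo (direction of
#' change) against the previous exam of the same eye.
#'
#' @param cohort A cohort tibble from [read_cohort()] or
#'   [simulate_cohort()].
#' @param points TeleROP-SS points allocation ([telerop_points()]).
#' @param table mROP-ActS lookup ([mrop_table()]).
#' @return The cohort with columns `telerop_score`, `telerop_reason`,
#'   `telerop_band`, `telerop_tw`, `telerop_tempo`, `mrop_score`,
#'   `mrop_reason`, `mrop_label`, `mrop_severe`, `mrop_tempo` appended.
#' @export
score_cohort <- function(cohort, points = telerop_points(),
                         table = mrop_table()) {
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$eye,
                           .data$exam_date)
  tele <- score_telerop(cohort[grading_columns()], points)
  mrop <- score_mrop(cohort[grading_columns()], table)
  scored <- dplyr::mutate(
    cohort,
    telerop_score = tele$score,
    telerop_reason = tele$no_score_reason,
    telerop_band = tele$band,
    telerop_tw = tele$tw_flag,
    mrop_score = mrop$score,
    mrop_reason = mrop$no_score_reason,
    mrop_label = mrop$label,
    mrop_severe = mrop$severe
  )
  scored |>
    dplyr::group_by(.data$subject_id, .data$eye) |>
    dplyr::mutate(
      telerop_tempo = tempo(dplyr::lag(.data$telerop_score),
                            .data$telerop_score),
      mrop_tempo = tempo(dplyr::lag(.data$mrop_score), .data$mrop_score)
    ) |>
    dplyr::ungroup()
}

scored_columns <- function() {
  c("telerop_score", "telerop_reason", "telerop_band", "telerop_tw",
    "telerop_tempo", "mrop_score", "mrop_reason", "mrop_label",
    "mrop_severe", "mrop_tempo")
}

#' Write a scored cohort to CSV
#'
#' Emits the long-layout input columns plus both systems' score columns (see
#' [score_cohort()]). The input columns round-trip through [read_cohort()].
#'
#' @param cohort A scored cohort from [score_cohort()], or an unscored
#'   cohort together with `results`.
#' @param path Output file path.
#' @param results Optional list with elements `telerop` and `mrop` (outputs
#'   of [score_telerop()] / [score_mrop()], one row per record) for callers
#'   that scored the cohort themselves; row counts must match.
#' @return `path`, invisibly.
#' @export
write_scored <- function(cohort, path, results = NULL) {
  if (!is.null(results)) {
    if (nrow(results$telerop) != nrow(cohort) ||
        nrow(results$mrop) != nrow(cohort)) {
      stop("results/record count mismatch")
    }
    cohort <- dplyr::mutate(
      cohort,
      telerop_score = results$telerop$score,
      telerop_reason = results$telerop$no_score_reason,
      telerop_band = results$telerop$band,
      telerop_tw = results$telerop$tw_flag,
      mrop_score = results$mrop$score,
      mrop_reason = results$mrop$no_score_reason,
      mrop_label = results$mrop$label,
      mrop_severe = results$mrop$severe
    )
    cohort <- cohort |>
      dplyr::group_by(.data$subject_id, .data$eye) |>
      dplyr::mutate(
        telerop_tempo = tempo(dplyr::lag(.data$telerop_score),
                              .data$telerop_score),
        mrop_tempo = tempo(dplyr::lag(.data$mrop_score), .data$mrop_score)
      ) |>
      dplyr::ungroup()
  }
  missing_cols <- setdiff(scored_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is not scored; missing: ",
         paste(missing_cols, collapse = ", "),
         " (run score_cohort() first)")
  }
  readr::write_csv(cohort[c(cohort_columns(), scored_columns())], path,
                   na = "")
  invisible(path)
}
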