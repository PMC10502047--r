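#' Load the modified ROP Activity Scale lookup table
#'
#' The modified ROP Activity Scale (mROP-ActS) assigns each bundled
#' (zone, stage, plus) combination a value from 0 (incomplete retinal
#' vascularization in any zone) to 22 (stage 5 in any zone) together with a
#' mild / moderate / severe label. Stages 1-3 are crossed with zone and plus;
#' stages 0, 4 and 5 are bundled endpoints, independent of plus (`plus =
#' "ANY"` rows). The scale predates Posterior Zone II, Pre-Plus and the
#' regression vocabulary, so no entries exist for those states.
#'
#' The bundled file is a synthetic reconstruction: the published
#' per-combination values appear only in supplementary material, so the
#' shipped table is built to satisfy every constraint the scale's published
#' description states (value range, stage-0/5 endpoints, stage-wise value
#' ranges, zone-wise plus increment sets). [validate_mrop_table()] checks a
#' table against all of those constraints and should be run on any
#' replacement transcription.
#'
#' @param path Optional path to an alternative lookup CSV with columns
#'   `zone`, `stage`, `plus`, `value`, `label`.
#' @return A tibble of lookup entries with a `provenance` attribute (the
#'   file's leading comment block).
#' @export
mrop_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mrop_acts_table_synthetic.csv",
                        package = "ropscore")
  }
  header <- readLines(path, n = 20)
  provenance <- sub("^#\\s*", "", header[startsWith(header, "#")])
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(zone = "character",
                                        stage = "character",
                                        plus = "character",
                                        value = "integer",
                                        label = "character"))
  tab <- tibble::as_tibble(tab)
  attr(tab, "provenance") <- paste(provenance, collapse = "\n")
  tab
}

#' Validate an mROP-ActS lookup table
#'
#' Checks every constraint the scale's published description states: values
#' are integers in 0-22; every zone has a stage-0 endpoint worth 0 and a
#' stage-5 endpoint worth 22 (the table maximum); zones I-III are fully
#' crossed with stages 1-3 and plus absent/present; stage-1 values lie in
#' 1-10, stage-2 in 2-12, stage-3 in 5-16; plus-bearing stage 1-3 entries lie
#' in 2-19; the plus increment across stages 1, 2, 3 is (5, 2, 0) in Zone I,
#' (8, 6, 0) in Zone II and (4, 3, 0) in Zone III; labels are mild, moderate
#' or severe; no Posterior Zone II or Pre-Plus entries exist; keys are
#' unique.
#'
#' @param table A lookup tibble as returned by [mrop_table()].
#' @return A findings tibble (`row`, `code`, `severity`, `message`); zero
#'   rows when the table passes.
#' @export
validate_mrop_table <- function(table) {
  f <- list(empty_findings())
  add <- function(rows, code, msg) {
    new_finding(rows, code, "error", msg)
  }
  bad <- which(is.na(table$value) | table$value < 0 | table$value > 22)
  if (length(bad)) f <- c(f, list(add(bad, "value_out_of_range",
                                      "values must lie in 0-22")))
  for (z in c("I", "II", "III")) {
    s0 <- table[table$zone == z & table$stage == "0", ]
    if (nrow(s0) == 0 || any(s0$value != 0)) {
      f <- c(f, list(add(0L, "missing_stage0_endpoint",
                         sprintf("zone %s lacks a stage-0 entry worth 0", z))))
    }
    s5 <- table[table$zone == z & table$stage == "5", ]
    if (nrow(s5) == 0 || any(s5$value != 22)) {
      f <- c(f, list(add(0L, "missing_stage5_endpoint",
                         sprintf("zone %s lacks a stage-5 entry worth 22", z))))
    }
  }
  if (nrow(table) > 0 && max(table$value, na.rm = TRUE) != 22) {
    f <- c(f, list(add(0L, "maximum_not_22", "table maximum must be 22")))
  }
  # full crossing of stages 1-3
  for (z in c("I", "II", "III")) for (s in c("1", "2", "3"))
    for (p in c("NONE", "PLUS")) {
      if (!any(table$zone == z & table$stage == s & table$plus == p)) {
        f <- c(f, list(add(0L, "missing_combination",
                           sprintf("no entry for zone %s stage %s plus %s",
                                   z, s, p))))
      }
    }
  ranges <- list("1" = c(1, 10), "2" = c(2, 12), "3" = c(5, 16))
  for (s in names(ranges)) {
    rows <- which(table$stage == s &
                    (table$value < ranges[[s]][1] |
                       table$value > ranges[[s]][2]))
    if (length(rows)) {
      f <- c(f, list(add(rows, paste0("stage", s, "_value_out_of_range"),
                         sprintf("stage-%s values must lie in %d-%d", s,
                                 ranges[[s]][1], ranges[[s]][2]))))
    }
  }
  rows <- which(table$stage %in% c("1", "2", "3") & table$plus == "PLUS" &
                  (table$value < 2 | table$value > 19))
  if (length(rows)) {
    f <- c(f, list(add(rows, "plus_value_out_of_range",
                       "plus-bearing entries must lie in 2-19")))
  }
  increments <- list(I = c(5, 2, 0), II = c(8, 6, 0), III = c(4, 3, 0))
  for (z in names(increments)) {
    inc <- vapply(c("1", "2", "3"), function(s) {
      with_p <- table$value[table$zone == z & table$stage == s &
                              table$plus == "PLUS"]
      without <- table$value[table$zone == z & table$stage == s &
                               table$plus == "NONE"]
      if (length(with_p) != 1 || length(without) != 1) return(NA_real_)
      with_p - without
    }, numeric(1))
    if (any(is.na(inc)) || !all(inc == increments[[z]])) {
      f <- c(f, list(add(0L, "plus_increment_mismatch",
                         sprintf("zone %s plus increments must be (%s)", z,
                                 paste(increments[[z]], collapse = ", ")))))
    }
  }
  bad <- which(!table$label %in% c("MILD", "MODERATE", "SEVERE"))
  if (length(bad)) f <- c(f, list(add(bad, "bad_label",
                                      "label must be MILD/MODERATE/SEVERE")))
  bad <- which(table$zone == "PII" | table$plus == "PRE")
  if (length(bad)) {
    f <- c(f, list(add(bad, "unsupported_state_entry",
                       "the scale has no Posterior Zone II or Pre-Plus entries")))
  }
  key <- paste(table$zone, table$stage, table$plus)
  dup <- which(duplicated(key))
  if (length(dup)) f <- c(f, list(add(dup, "duplicate_key",
                                      "duplicate (zone, stage, plus) entry")))
  dplyr::bind_rows(f)
}

#' Score gradings with the modified ROP Activity Scale
#'
#' A pure lookup: the grading's (zone, stage, plus) is matched against the
#' bundled table, collapsing detachment subtypes (4A/4B to 4, 5A-5C to 5)
#' onto the scale's bundled endpoints, which ignore plus. Gradings the scale
#' predates — Posterior Zone II, Pre-Plus, any regression state,
#' reactivation — return a typed no-score (`UNMAPPED_COMBINATION`); gradings
#' missing a required field return `MISSING_FIELDS`.
#'
#' @param grading Grading tibble from [eye_grading()]. Must pass
#'   [validate_grading()] with no errors.
#' @param table Lookup table from [mrop_table()].
#' @return A tibble with one row per grading: `system` (`"MROP_ACTS"`),
#'   `score` (integer value 0-22, `NA` when no score), `no_score_reason`,
#'   `label` (the entry's severity label), `severe` (label is `"SEVERE"`).
#' @examples
#' score_mrop(eye_grading("II", "0", "NONE"))    # 0, the scale minimum
#' score_mrop(eye_grading("PII", "3", "PLUS"))   # no score: unmapped
#' @export
score_mrop <- function(grading, table = mrop_table()) {
  findings <- validate_grading(grading)
  errs <- findings[findings$severity == "error", ]
  if (nrow(errs) > 0) {
    stop("invalid gradings (rows ", paste(unique(errs$row), collapse = ", "),
         "): ", errs$message[1])
  }
  n <- nrow(grading)
  value <- rep(NA_integer_, n)
  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  missing <- is.na(grading$zone) | is.na(grading$stage) | is.na(grading$plus)
  reason[missing] <- "MISSING_FIELDS"

  unmapped <- !missing &
    ((grading$zone == "PII") | (grading$plus == "PRE") |
       (!is.na(grading$regression) & grading$regression != "NONE") |
       (!is.na(grading$reactivation) & grading$reactivation))
  reason[unmapped] <- "UNMAPPED_COMBINATION"

  todo <- which(!missing & !unmapped)
  if (length(todo)) {
    stage_key <- substr(grading$stage[todo], 1, 1)  # 4A -> 4, 5C -> 5
    endpoint <- stage_key %in% c("0", "4", "5")
    plus_key <- ifelse(endpoint, "ANY",
                       ifelse(grading$plus[todo] == "PLUS", "PLUS", "NONE"))
    key <- paste(grading$zone[todo], stage_key, plus_key)
    tab_key <- paste(table$zone, table$stage, table$plus)
    hit <- match(key, tab_key)
    value[todo] <- table$value[hit]
    label[todo] <- table$label[hit]
    reason[todo[is.na(hit)]] <- "UNMAPPED_COMBINATION"
  }
  tibble::tibble(
    system = "MROP_ACTS",
    score = value,
    no_score_reason = reason,
    label = label,
    severe = ifelse(is.na(label), NA, label == "SEVERE")
  )
}
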