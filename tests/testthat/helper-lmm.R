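# longitudinal score series generated directly from a mixed-model class:
# subject random intercepts (sd 8), optional random slopes around a fixed
# decline of 1.5 points/week, residual sd 4; shaped like a scored cohort so
# fit_longitudinal_models() can consume it
simulate_lmm_scores <- function(n_subjects, slope_sd = 0, n_exams = 5,
                                eye = "OD") {
  subj <- sprintf("L%03d", seq_len(n_subjects))
  intercepts <- rnorm(n_subjects, 40, 8)
  slopes <- -1.5 + rnorm(n_subjects, 0, slope_sd)
  rows <- lapply(seq_len(n_subjects), function(i) {
    pma <- seq(31, by = 2, length.out = n_exams)
    tibble::tibble(
      subject_id = subj[i], eye = eye, pma_weeks = pma,
      ega_weeks = rnorm(1, 28.2, 2), birth_weight_g = rnorm(1, 1129, 300),
      telerop_score = intercepts[i] + slopes[i] * (pma - 36) +
        rnorm(n_exams, 0, 4),
      telerop_tw = FALSE
    )
  })
  dplyr::bind_rows(rows)
}
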