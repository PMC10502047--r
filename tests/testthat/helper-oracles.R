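# Reference severity table: every published (zone, stage, plus) combination
# row with its score and band. "0" is incomplete vascularization; the AROP
# row is flagged separately; adverse rows apply in any zone.
severity_reference <- function() {
  rows <- c(
    "ANY,5C,NONE,100,ADVERSE", "ANY,5B,NONE,95,ADVERSE",
    "ANY,5A,NONE,90,ADVERSE", "ANY,4B,NONE,89,ADVERSE",
    "ANY,4A,NONE,86,ADVERSE",
    "I,3,PLUS,85,TREATMENT_WARRANTED", "AROP,1,PLUS,85,TREATMENT_WARRANTED",
    "PII,3,PLUS,75,TREATMENT_WARRANTED", "I,2,PLUS,70,TREATMENT_WARRANTED",
    "II,3,PLUS,70,TREATMENT_WARRANTED", "I,1,PLUS,63,TREATMENT_WARRANTED",
    "I,3,PRE,60,TREATMENT_WARRANTED", "I,0,PLUS,60,TREATMENT_WARRANTED",
    "PII,2,PLUS,60,TREATMENT_WARRANTED", "I,3,NONE,55,TREATMENT_WARRANTED",
    "II,2,PLUS,55,TREATMENT_WARRANTED",
    "PII,1,PLUS,53,HIGH", "PII,3,PRE,50,HIGH", "PII,0,PLUS,50,HIGH",
    "II,1,PLUS,48,HIGH", "I,2,PRE,45,HIGH", "II,3,PRE,45,HIGH",
    "PII,3,NONE,45,HIGH", "II,0,PLUS,45,HIGH", "I,2,NONE,40,HIGH",
    "II,3,NONE,40,HIGH",
    "I,1,PRE,38,MODERATE", "I,0,PRE,35,MODERATE", "PII,2,PRE,35,MODERATE",
    "I,1,NONE,33,MODERATE", "I,0,NONE,30,MODERATE", "PII,2,NONE,30,MODERATE",
    "II,2,PRE,30,MODERATE", "PII,1,PRE,28,MODERATE",
    "PII,0,PRE,25,LOW", "II,2,NONE,25,LOW", "PII,1,NONE,23,LOW",
    "II,1,PRE,23,LOW", "II,0,PRE,20,LOW", "PII,0,NONE,20,LOW",
    "II,1,NONE,18,LOW", "II,0,NONE,15,LOW"
  )
  parts <- do.call(rbind, strsplit(rows, ","))
  tibble::tibble(
    zone = ifelse(parts[, 1] %in% c("ANY", "AROP"), "II", parts[, 1]),
    stage = parts[, 2],
    plus = parts[, 3],
    arop = parts[, 1] == "AROP",
    any_zone = parts[, 1] == "ANY",
    score = as.integer(parts[, 4]),
    band = parts[, 5]
  )
}

# independent additive oracle written directly from the published points
# allocation; deliberately scalar and branch-explicit
telerop_oracle <- function(zone, stage, plus, regression = "NONE",
                           arop = FALSE) {
  adverse <- c("4A" = 86, "4B" = 89, "5A" = 90, "5B" = 95, "5C" = 100)
  if (!is.na(stage) && stage %in% names(adverse)) {
    return(unname(adverse[stage]))
  }
  if (isTRUE(arop)) return(85)
  if (is.na(zone) || zone == "III") return(NA_real_)
  zp <- c(I = 30, PII = 20, II = 15)[[zone]]
  sp <- if (!is.na(regression) && regression != "NONE") {
    10
  } else {
    c("0" = 0, "1" = 3, "2" = 10, "3" = 25)[[stage]]
  }
  pp <- c(NONE = 0, PRE = 5, PLUS = 30)[[plus]]
  zp + sp + pp
}

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# brute-force average (mid) ranks: each permutation that sorts x
# non-decreasingly places element p[k] at position k; ties average their
# positions over all qualifying permutations
perm_ranks <- function(x) {
  n <- length(x)
  perms <- all_perms(n)
  pos_sum <- numeric(n)
  hits <- 0
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (!is.unsorted(x[p])) {
      pos_sum[p] <- pos_sum[p] + seq_len(n)
      hits <- hits + 1
    }
  }
  pos_sum / hits
}

# Spearman rho from first principles: Pearson product-moment formula applied
# to the brute-forced average ranks
spearman_oracle <- function(x, y) {
  rx <- perm_ranks(x)
  ry <- perm_ranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# every valid grading combination in the additive + override universe
grading_universe <- function() {
  active <- expand.grid(zone = c("I", "PII", "II", "III"),
                        stage = c("0", "1", "2", "3"),
                        plus = c("NONE", "PRE", "PLUS"),
                        regression = c("NONE", "REGRESS", "REGRESS-VEGFI",
                                       "REGRESS-LASER"),
                        arop = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  detached <- expand.grid(zone = c("I", "PII", "II", "III"),
                          stage = c("4A", "4B", "5A", "5B", "5C"),
                          plus = c("NONE", "PRE", "PLUS"),
                          regression = "NONE", arop = FALSE,
                          stringsAsFactors = FALSE)
  dplyr::bind_rows(tibble::as_tibble(active), tibble::as_tibble(detached))
}
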