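---
title: "Methods: scoring models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropscore)
```

## The severity score

The telemedicine severity score treats the three ICROP axes that drive
treatment decisions — zone, stage, plus disease — as independently weighted,
additive contributions:

$$S = Z + G + P, \qquad
Z \in \{30, 20, 15\},\;
G \in \{0, 3, 10, 25\} \cup \{10_{\text{regress}}\},\;
P \in \{0, 5, 30\}.$$

Zone I and Plus carry 30 points each and stage 3 carries 25, so the three
strongest treatment drivers dominate the sum. Two overrides sit outside the
additive branch, in fixed precedence:

1. **Detachment stages** (4A–5C) map to fixed scores 86, 89, 90, 95, 100 in
   the reserved adverse band. These outcomes are not amenable to preventive
   treatment, so they outrank everything else, including AROP.
2. **AROP** scores 85 — the top of the treatment-warranted band — whatever
   the zone, stage and plus recorded alongside it.

Everything else is the additive sum. Two conventions make the sum total:

* **Regression replaces stage.** A regressed eye (spontaneous, post-anti-VEGF
  or post-laser) contributes 10 stage points in place of the active-stage
  points, and still adds its zone and plus points. The points allocation
  lists regression inside the stage column, which is what licenses treating
  it as a stage substitute rather than an additional term. A consequence we
  flag rather than hide: a regressed Zone II eye retaining full Plus scores
  15 + 10 + 30 = 55 and is therefore flagged treatment-warranted. Whether
  that flag is clinically wanted is genuinely open; the scorer follows the
  threshold rule and the flag is visible in the output for reviewers to
  judge.
* **Reactivation variants score like their base categories** (reactivated
  stage 2 scores 10, reactivated Pre-Plus scores 5, and so on).

Scores are integers and the risk bands are closed integer intervals — low
0–25, moderate 26–39, high 40–54, treatment warranted 55–85, adverse
86–100 — so band edges are unambiguous without tie-break rules. The additive
branch cannot produce a value below 15 (Zone II, incomplete vascularization,
no plus) or above 85 (Zone I, stage 3, Plus); the band function nevertheless
accepts 0–14 so future amendments can extend the scale downward without an
interface change.

Zone III returns a typed no-score (`ZONE_III_UNSUPPORTED`) instead of a
silent zero or an error: wide-field photographic screening cannot reliably
image Zone III, and a typed refusal keeps coverage statistics honest.
Missing fields likewise yield `MISSING_FIELDS` — but only when the branch
taken actually needs the field: a stage-5C grading needs no zone, and a
regressed eye needs no stage.

The points ship as a versioned plain-text file
(`inst/extdata/telerop_points.csv`) so ICROP amendments are data edits.

## The comparator

The modified ROP activity scale is a pure lookup over bundled
(zone, stage, plus) combinations: stages 1–3 are crossed with zones I–III
and plus absent/present; stages 0, 4 and 5 are plus-independent endpoints
worth 0, 20 and 22. Detachment subtypes collapse onto the endpoints
(4A/4B → 4, 5A–5C → 5). Four grading classes predate the scale and return
`UNMAPPED_COMBINATION`: Posterior Zone II, Pre-Plus, regression and
reactivation.

The published per-combination values appear only in supplementary material
we do not redistribute, so the bundled table is a **synthetic
reconstruction**. It is constrained by everything the scale's description
states in print: values 0–22 with the stage-0 and stage-5 anchors; stage-1
entries within 1–10, stage-2 within 2–12, stage-3 within 5–16; plus
increments across stages 1→3 of {5, 2, 0} in Zone I, {8, 6, 0} in Zone II
and {4, 3, 0} in Zone III (the value of plus falls as stage rises); and
monotone severity in zone and stage. `validate_mrop_table()` enforces all of
these plus structural completeness, so a future transcription of the real
supplement can be dropped in and verified loudly. One printed constraint —
plus-bearing entries "ranging 2 to 19" — cannot be an attained range
simultaneously with the stage-wise caps and the zero stage-3 increments; we
implement it as a containment check (all plus-bearing stage 1–3 entries lie
inside [2, 19]).

Severity labels per entry are likewise supplement-only; the reconstruction
labels by value (≥ 10 severe, 5–9 moderate, ≤ 4 mild), chosen so that every
treatment indication the scale *can* express carries a severe label.

**Identification rule.** For treatment-warranted accuracy the comparator's
"identified" criterion is not stated precisely in print. The default rule is
*severe-label*: the scale identifies a treated eye only if some exam at or
before treatment returns an entry labelled severe. A *threshold* rule
(value ≥ cut-off, default 10) is available as a configuration for
sensitivity analyses. Either way, an exam returning no score can never
identify a case — that is the mechanism by which Posterior Zone II eyes are
missed.

## Comparison statistics

* **Score-return rate**: numeric scores over graded eye-exams, per eye and
  overall. An empty cohort yields a typed `NA`, not zero.
* **TW accuracy**: a *case* is one treated eye (the published per-eye
  accuracy tables are consistent only with eye-level cases). Exams strictly
  after the treatment date are excluded: post-treatment regression would
  deflate the measure spuriously. Misses are returned with a reason
  (`NO_SCORE_RETURNED` vs `BELOW_RULE`).
* **Spearman correlation** uses mid-ranks for ties (`stats::cor`,
  `method = "spearman"`); pairs with a no-score on either side are excluded
  and counted, and fewer than three complete pairs yields `NA`. The test
  suite checks the implementation against a brute-force oracle that derives
  average ranks by enumerating all permutations (n ≤ 8) and applies the
  product-moment formula by hand. Per-eye and pooled coefficients are both
  reported, since a published "overall" correlation may be either.
* **Longitudinal trends** are linear mixed-effects models per eye
  laterality, fitted with `lme4` by maximum likelihood (not REML) so AIC
  values are comparable across fixed-effect structures. The default
  candidate set is (a) fixed PMA trend + random subject intercepts, (b) a +
  random PMA slopes, (c) b + gestational age and birth weight as fixed
  covariates, (d) b + quadratic PMA. The candidate set is config-driven —
  the tested contract is the selection machinery (fit all, report AIC and
  convergence/singularity per candidate, select the minimum-AIC converged
  candidate), not the specific four formulas. PMA enters centred at 36
  weeks to keep the intercept interpretable and the optimizer well-scaled.
  With one exam per subject no candidate is identifiable and the selection
  reports that; with two, the random-intercept model fits while
  random-slope candidates correctly fail.

## The cohort simulator

`simulate_cohort()` exists so every downstream statistic is testable against
a known ground truth without any data download. It emulates the *structure*
of a NICU telemedicine screening cohort, and its defaults are fixed at the
published descriptors of such a population: gestational age 28.2 (SD 2.0)
weeks, birth weight 1129 (SD 300) g, 54% male, serial exams every 7–14 days
from 31 weeks postmenstrual age, screening ending by 45 weeks or after
discharge criteria.

Disease dynamics are a first-order weekly Markov chain per eye over
(zone, stage, plus, regression, reactivation) with monotone ±1 stage steps,
an absorbing full-regression state, optional detachment progression
(4A → … → 5C) for untreated stage-3-plus eyes, and treatment triggered at
the first exam in the treatment-warranted band (`treat_when_tw`). Weekly
rates convert to per-interval probabilities as
$1-(1-p)^{d/7}$. This is fixture machinery: the transition rates are not
calibrated to natural-history data, and we chose them once so the emergent
cohort matches the published screening descriptors — roughly 7 exams per
infant, a treated-eye fraction near 7%, and about 19–21% of eye-exams
carrying a state the activity scale cannot map, mirroring the reported
~80% comparator return rate.

Two modelling choices deserve emphasis:

* **Posterior Zone II and Pre-Plus are recording refinements, not Markov
  states.** Each eye-exam draws one uniform variate: with probability
  `pii_fraction` a Zone II exam is recorded as Posterior Zone II, else with
  probability `preplus_fraction` a no-plus exam is recorded as Pre-Plus
  (disjoint intervals of the same draw). The comparison statistics depend
  only on the *marginal exposure* to these states, and this design makes
  that exposure exactly the configured fractions — testable within binomial
  error — rather than an emergent property of a transient chain. The cost is
  realism: real Pre-Plus is a stage in plus evolution, and real posterior
  disease persists within an eye; the simulator's plus chain jumps
  NONE → PLUS directly, and PII draws are independent across exams.
* **Eye-level posterior forcing.** `force_pii_treated` records *every* exam
  of every treated eye as Posterior Zone II. The comparator's published
  failure mode is described at eye level ("eyes classified as Posterior
  Zone II"), and only the eye-level version guarantees the comparator misses
  the whole pre-treatment history; forcing only the treatment exam would
  leave earlier severe-labelled exams identifiable.

Reproducibility: each subject's trajectory is drawn from its own seed
derived from the cohort seed and the subject index, so subject k is
identical whether the cohort has 20 or 2000 subjects, and every output is
byte-identical under a repeated seed.

What passing tests on simulated cohorts do **not** show: that the severity
score's accuracy advantage has the published effect size on real data, that
the transition rates match ROP natural history, or that grader variability
(absent here) leaves the comparisons intact.

## Numerical and interface choices

* Scores and lookup values are integers end-to-end; no floating-point band
  edges exist.
* PMA derives as `ega + days/7` rounded to one decimal week; when both PMA
  and dates are supplied they must agree within 0.05 weeks or the reader
  refuses the row.
* CSV serialization uses ISO-8601 dates, UTF-8, and the grading tokens of
  the published tables (`I`, `PII`, `II`, `III`; `0`–`3`, `4A`–`5C`;
  `NONE`, `PRE`, `PLUS`; `REGRESS[-VEGFI|-LASER]`), so fixtures are readable
  against the source material; blank cells become `NA`, never defaults.
  Round-trips are field-exact and tested.
* Validation returns findings (code, severity, message) rather than raising,
  so callers decide what blocks scoring. Reactivation without recorded
  regression history is a warning, not an error: a standalone
  cross-sectional record cannot prove the history either way.
* Problem sizes in the test suite — cohorts of 12–300 subjects, 50
  mixed-model replicates at 200 subjects, permutation oracles to n = 8 —
  were chosen as the smallest sizes at which the binomial and
  model-selection checks have comfortable margins.

## Known limitations

* The activity-scale table is a constrained reconstruction, not the
  published supplement; per-combination values may differ from the original
  even though every printed constraint holds. The published cohort-level
  accuracy figures (e.g. 66.7% comparator accuracy) therefore cannot be
  reproduced desk-side and are not claimed by any test; reproducing them
  requires the deposited cohort and the original supplement.
* Extent (clock hours) and plus quadrants are carried through I/O but never
  scored, matching the scoring systems themselves.
* The simulator models neither grader disagreement nor missed visits, and
  its treatment policy is deterministic.
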