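# ropscore

Severity and activity scoring for retinopathy of prematurity (ROP)
telemedicine screening.

ROP is a vasoproliferative retinal disease of preterm infants. Telemedicine
screening programs photograph infants' retinas in the NICU and have the
images graded remotely using the International Classification of ROP
(ICROP): a **zone** (how posterior the disease is), a **stage** (lesion
severity, 0–5), **plus disease** (posterior-pole vascular dilation and
tortuosity, with an intermediate *Pre-Plus* state), and modifiers for
aggressive ROP (AROP), regression after treatment or spontaneously, and
reactivation. The people acting on those gradings — neonatologists, nurses,
families — are mostly not ROP specialists, so a single severity number with
named risk bands communicates far better than a triple of ICROP terms.

`ropscore` is aimed at screening programs and methods researchers who need
such a score as software: a scoring engine, a comparator, a longitudinal
data model, a cohort simulator, and the statistics to compare scoring
systems on a cohort.

## The two scoring systems

**Telemedicine ROP severity score** (`score_telerop()`) is additive over
independently weighted ICROP elements:

| element | points |
|---|---|
| Zone I / Posterior Zone II / Zone II | 30 / 20 / 15 |
| Stage 0 / 1 / 2 / 3 | 0 / 3 / 10 / 25 |
| Regression (any kind, replaces stage points) | 10 |
| Plus: none / Pre-Plus / Plus | 0 / 5 / 30 |

so `score = zone + stage + plus`, with two overrides: AROP scores 85, and
detachment stages 4A/4B/5A/5B/5C score 86/89/90/95/100 in the reserved
adverse band. Reactivation variants score like their base categories. The
additive range is 15 (Zone II, incomplete vascularization, no plus) to 85
(Zone I, stage 3, plus). Risk bands are closed integer intervals: low 0–25,
moderate 26–39, high 40–54, **treatment warranted 55–85**, adverse 86–100.
The weights are chosen so that every accepted treatment indication — and
nothing milder — reaches 55 (`treatment_indication_scores()` enumerates all
six and proves the minimum). Zone III gradings return a typed no-score: the
score is designed for wide-field photographic exams, which cannot reliably
image Zone III.

**Modified ROP activity scale** (`score_mrop()`) is the comparator: a
bundled lookup from (zone, stage, plus) to a 0–22 value with a
mild/moderate/severe label. It predates Posterior Zone II, Pre-Plus and the
regression vocabulary, so those gradings return a typed
`UNMAPPED_COMBINATION` — the mechanism behind its incomplete score-return
rate on real cohorts. The published per-combination values live in
supplementary material, so the bundled table
(`inst/extdata/mrop_acts_table_synthetic.csv`) is a **synthetic
reconstruction** satisfying every constraint stated in print;
`validate_mrop_table()` checks any replacement transcription against all of
them.

## Worked example

```r
library(ropscore)

exam <- eye_grading(zone = c("I", "PII", "II"), stage = c("3", "2", "0"),
                    plus = c("PLUS", "PRE", "NONE"))
score_telerop(exam)
#>   system     score no_score_reason band                tw_flag
#> 1 TELEROP_SS    85 <NA>            TREATMENT_WARRANTED TRUE
#> 2 TELEROP_SS    35 <NA>            MODERATE            FALSE
#> 3 TELEROP_SS    15 <NA>            LOW                 FALSE
score_mrop(exam)
#>   system    score no_score_reason      label  severe
#> 1 MROP_ACTS    16 <NA>                 SEVERE TRUE
#> 2 MROP_ACTS    NA UNMAPPED_COMBINATION <NA>   NA
#> 3 MROP_ACTS     0 <NA>                 MILD   FALSE
```

The first eye (Zone I, stage 3, plus) is treatment-warranted at the additive
ceiling of 85; the second (Posterior Zone II, stage 2, Pre-Plus) gets a
moderate-risk 35 from the severity score but no value at all from the
activity scale; the third is a healthy immature eye at the floor of 15.

Cohort level — simulate a screening population, score every eye-exam with
both systems, and compare them:

```r
sim    <- simulate_cohort(sim_config(n_subjects = 60, seed = 42))
report <- build_report(sim$cohort, fit_models = FALSE)
report$return_rate$telerop$overall   #> 1
report$return_rate$mrop$overall      #> 0.7719715
report$spearman$pooled$rho           #> 0.9888339
summarise_accuracy(report)
#> TW-ROP identification accuracy
#>            mROP-ActS  TeleROP-SS
#> Overall         1.00        1.00
#> Right eye       1.00        1.00
#> Left eye        1.00        1.00
```

The severity score returns a value for every graded eye-exam, while the
activity scale loses the Posterior Zone II / Pre-Plus / regression exams
(~23% under the simulator's defaults); where both systems return a score
they rank eyes almost identically. `fit_longitudinal_models()` adds
AIC-selected linear mixed-effects trends over postmenstrual age (random
intercepts/slopes per subject) for the longitudinal analysis.

A command-line front end covering the same pipeline ships in
`inst/exec/ropscore` (`score`, `compare`, `simulate` subcommands).

## Scope

The package scores gradings; it does not grade images. Image acquisition,
deep-learning vascular-severity mapping, and prospective validation are out
of scope. The simulator's disease dynamics are deliberately simple fixture
machinery (see the methods vignette, `vignettes/ropscore-methods.Rmd`), not
a calibrated natural-history model.
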