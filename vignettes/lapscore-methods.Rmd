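---
title: "Scoring, grading and validating difficult laparoscopic cholecystectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, grading and validating difficult laparoscopic cholecystectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapscore)
```

## The clinical problem

Laparoscopic cholecystectomy (LC) is the standard operation for
symptomatic gallstones, but a minority of cases turn out to be
technically difficult — prolonged dissection, bile or stone spillage,
injury to the cystic duct or artery, or conversion to open surgery.
Anticipating these cases preoperatively helps with theatre planning,
consent and referral.  `lapscore` implements a widely used nine-parameter
preoperative risk score, the intraoperative difficulty grading used to
validate it, and the complete diagnostic-validation analysis, together
with a synthetic-cohort generator so every stage can be exercised and
tested without patient data.

## The preoperative score

Nine findings from history, examination and ultrasound contribute
integer points (total range 0–12): age (> 50 y: 1), sex (male: 1), prior
hospitalization for cholecystitis (1), BMI (< 25: 0; 25–27.5: 1;
> 27.5: 2 kg/m²), palpable gallbladder (1), abdominal scar (none: 0;
infraumbilical: 1; supraumbilical: 2), gallbladder wall > 4 mm on
ultrasound (2), impacted stone (1), pericholecystic collection (1).
A total **strictly greater than 3** predicts a difficult operation.

Two boundaries are not fixed by the printed bands and are resolved as
documented, configurable conventions:

* **BMI exactly 25** scores 1 (the middle band is taken closed below)
  and **exactly 27.5** scores 1 (the top band is written strictly
  "> 27.5").  We take printed inequalities literally.
* **Age exactly 50** scores 0 (the high band is strictly "> 50");
  `age_inclusive = TRUE` flips this.

A descriptive three-way category (easy / difficult / very difficult by
total score) exists in the source scoring tradition but with unstated
boundaries; since every validation analysis uses the binary `> 3` rule,
`categorize_preop()` defaults to the cosmetic bands ≤ 5 / 6–9 / ≥ 10 and
makes them an explicit argument rather than guessing an authoritative
split.

## Intraoperative grading

Four objective criteria grade the operation: operative time (< 60 min
easy, 60–120 difficult, > 120 very difficult), bile or stone spillage
(difficult), duct **or** artery injury (difficult; **both** very
difficult), and conversion to open surgery (very difficult).  Three
choices were genuinely open:

* **Aggregation.**  The criteria are listed per column without an
  explicit combination rule.  We grade by **maximum severity**: any
  single very-difficult marker makes the case very difficult.  This is
  the only rule consistent with counting every conversion in the
  difficult group of the validation analyses.
* **Boundary minutes.**  "< 60 / 60–120 / > 120" leaves 60 and 120 to
  convention; both fall in the middle band, making the bands exhaustive.
* **Isolated artery injury** is graded difficult, i.e. at the same
  severity as an isolated duct injury: validation tables count all
  artery injuries in the difficult group, and only the combined injury
  is listed under very difficult.

Difficult and very difficult cases are pooled into one "difficult"
outcome for all validation analyses (`dichotomize_grade()`), because ROC
analysis needs a binary outcome and very difficult cases are rare.
Subjective technical-difficulty observations (port entry, adhesiolysis,
Calot's dissection, …) are deliberately outside the grade.

## Statistical methods

All tests are implemented in the package and return base-R `htest`
objects; reference implementations (`fisher.test`, `chisq.test`,
`wilcox.test`, `glm`, `pROC`) appear only as independent cross-checks in
the test suite.

* **Fisher's exact test** (2×2) uses the two-sided *probability-mass*
  rule: the p-value sums hypergeometric probabilities of all tables with
  the observed margins that are no more probable than the observed table
  (ties admitted within a relative tolerance of 10⁻⁷).  This is the
  convention that reproduces standard clinical-software output.
* **Pearson chi-square** is computed *without* continuity correction —
  the corrected statistic would not reproduce standard 2×2 output
  (e.g. it moves the hospitalization table's p from 0.025 to ≈ 0.042).
  Zero expected counts raise an error pointing at the exact tests.
* **Freeman–Halton** extends the exact test to r×c by full enumeration
  of tables with the observed margins; an explicit `max_tables` bound
  (default 2·10⁶) aborts rather than run unboundedly.
* **Mann–Whitney U** uses midranks; exact two-sided p (twice the smaller
  tail, capped at 1) when there are no ties and `n_x·n_y ≤ 400`,
  otherwise the tie-corrected normal approximation without continuity
  correction.
* **Spearman's rho** is the Pearson correlation of midranks with the
  usual t approximation; constant input is flagged undefined rather than
  silently numeric.
* **Normality screening** uses the one-sample Kolmogorov–Smirnov
  statistic against a normal with plug-in mean and SD.  Because the
  parameters are estimated from the same sample the asymptotic p-value
  is approximate (anti-conservative versus Lilliefors tables); it is
  labelled as such and used only to choose between t and Mann–Whitney in
  the report pipeline, never as a primary result.

### Diagnostic accuracy

Sensitivity, specificity, PPV, NPV and accuracy come with
**Clopper–Pearson exact intervals** (beta quantiles).  The exact method
is deliberate: published intervals of this validation design (e.g.
37.2–75.5 % about a sensitivity of 57.14 % = 16/28) are asymmetric and
match the exact interval, not Wald or Wilson.  Zero denominators flag
the metric undefined instead of propagating `NaN`.

The ROC curve takes the positivity rule "score **>** threshold"
(strict), so the clinical cutoff "> 3" is literally a curve threshold.
AUC is trapezoidal; its SE and CI use DeLong's placement-value method.
The operating cutoff is chosen by the **Youden index** J = sensitivity +
specificity − 1, ties broken toward higher specificity.

### Confusion-table reconstruction

Published validation tables often print only rounded metrics.
`reconstruct_confusion_table()` enumerates every integer table (tp, fp,
fn, tn) at the stated cohort size and keeps those whose metrics round
**half-up** to the printed values at their printed precision; a printed
metric constrains only tables where its denominator is positive.  The
result is reported explicitly as unique / ambiguous (all candidates
listed) / none — never a silent pick.  At n = 150 with specificity
79.51 %, PPV 39 % and NPV 89 % the solution is unique — (16, 25, 12, 97)
— and reproduces sensitivity 57.14 % with exact CI 37.2–75.5 %.  Note
that an NPV of 85 % (which appears alongside 89 % in the source
tradition's tables) is *inconsistent* with the other printed metrics:
the same enumeration returns "none".  The package treats 89 % as the
internally consistent value and lets the reconstruction surface such
discrepancies.

### Sample size

`sample_size_diagnostic()` implements the Buderer formula
`n = ⌈z²·p(1−p)/d²/prev⌉` (sensitivity; `1−prev` for specificity).
Prevalence is an explicit argument: published sample sizes computed from
this formula are not reproducible without knowing the assumed
prevalence, so the package asserts the formula, not any particular
printed n.

### Logistic regression

`fit_logistic()` maximizes the binomial likelihood by Newton/IRLS:
start at zero, tolerance 10⁻⁸ on the score or the relative
log-likelihood change, at most 50 iterations, step-halving (up to 10
halvings) so the log-likelihood never decreases — all deterministic.
Standard errors come from the inverse observed information; odds ratios
are `exp(β)` with Wald intervals `exp(β ± z·SE)`.  **Quasi-complete
separation** — common with sparse surgical-complication cells — is
detected by fitted probabilities pinned at 0/1 or a diverging
coefficient with a vanished gradient; the fit is returned with a warning
and a `separation` flag, reproducing the *phenomenon* of exploding Wald
intervals rather than hiding it.  A Firth (Jeffreys-prior) penalty is
available behind `firth = TRUE` as a remedial option; plain ML is the
default because that is what the validation analyses this package
mirrors evidently used.

One modelling caveat is flagged rather than emulated: regressing the
observed difficulty grade on the *intraoperative* variables that define
it (operative time, spillage, …) is circular.  `run_study()` therefore
defaults to preoperative predictors (score total, hypertension, prior
hospitalization, wall thickening, pericholecystic collection); the
predictor list is configuration.

## The synthetic-cohort generator

`generate_cohort()` emulates the *marginal* structure of a 150-patient
elective LC series: 81.33 % female, 16 % over 50, BMI bands
38 / 60.67 / 1.33 %, scars 75.33 / 23.33 / 1.33 %, hospitalization
25.33 %, palpable gallbladder 0.67 %, thickened wall 12.67 %, impacted
stone 0.67 %, pericholecystic collection 3.33 %, hypertension 4.67 %,
diabetes 8.67 % — stored as exact cohort fractions (x/150) so that
multi-level sets sum to one.  Latent difficulty is Bernoulli with
logistic probability: slopes are clinically plausible effect sizes
(strongest, 1.5 log-odds, for thickened wall and pericholecystic
collection) and the intercept (−2.01) is calibrated once so the expected
difficult fraction is 28 % (the 24.7 % + 3.3 % of the emulated series).
Difficult cases become very difficult with probability 5/42.
Intraoperative findings are drawn conditional on the latent grade:
operative time uniform within the grade's band (easy U(20,60), difficult
U(60,120), very difficult U(120,180) minutes — the bands are the grading
table's, the within-band law is our choice), spillage and injury
probabilities at the difficult-group frequencies of the emulated series,
and conversion exactly in the very difficult grade.  With these defaults
`grade_operation()` applied to the generated findings reproduces the
latent grade, so generator and grader stay consistent.

What the generator does **not** emulate: the joint distribution of risk
factors (draws are independent; a Gaussian-copula correlation hook was
considered and deliberately left out of the defaults as it goes beyond
what the marginals support), within-patient clinical coherence beyond
the difficulty model, and the real series' per-patient data.  Passing
tests on synthetic cohorts therefore demonstrate that the *machinery* is
correct and calibrated, not that the score performs identically on real
patients.  The mean-score summary "2.55 ± 2.55" of the emulated series
is not a calibration target: a mean and SD alone do not pin down the
score distribution.

All randomness is seeded (`Mersenne-Twister`, fixed `sample.kind`), the
caller's RNG state is restored, and the canonical test fixture
(`fixture_150()`, seed 150) is pinned by a frozen fingerprint so
generator drift fails loudly.

## Numerical choices and problem sizes

* Exact-test tie comparisons use a relative tolerance of 10⁻⁷;
  enumeration in the Freeman–Halton test is bounded by `max_tables`.
* Reconstruction rounding is half-up with an absolute guard of 10⁻⁹
  against floating-point edge cases.
* IRLS weights are floored at 10⁻¹² to keep the information matrix
  finite under separation.
* The test suite validates exact tests against brute-force enumeration
  over *all* 2×2 tables with total ≤ 30 (≈ 46 000 tables), coverage of
  the exact intervals on 3 000–4 000 seeded replicates per setting,
  logistic parameter recovery at n = 2 000, generator calibration at
  n = 15 000, and Fisher-vs-chi-square asymptotic agreement on tables
  with cells in the thousands (the two-sided exact p approaches the
  Pearson p only at O(n^(−1/2))).  These sizes keep every property
  estimate's Monte-Carlo error well below its assertion margin.

## Known limitations

* The exact-test enumeration is exponential in the table dimensions;
  r×c tables beyond a few hundred enumerable tables per margin set
  should use the chi-square test (the error message says so).
* The KS normality p-value is approximate by construction (plug-in
  parameters) and is not exposed as a primary inferential result.
* DeLong variance is undefined for degenerate single-observation
  classes; the curve is still returned with `auc_se = 0` in that case.
* Published AUC/SE/correlation values of any particular study cannot be
  recomputed without per-patient scores; the package asserts the
  defining properties of those estimators instead (AUC ≡ normalized
  Mann–Whitney U, DeLong agreement with the reference implementation).
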