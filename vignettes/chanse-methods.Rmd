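---
title: "Methods: scoring, diagnostic accuracy, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, diagnostic accuracy, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chanse)
```

## The problem and the scores

Acute appendicitis in children is diagnosed from a combination of symptoms,
physical findings, and inflammatory markers, but classic supine signs (psoas,
obturator, Rovsing's) have limited value and can be hard to elicit in an
anxious child. The CHANSE score is a six-item bedside score built around the
heel drop test — a standing maneuver in which the patient drops abruptly from
tiptoe to heels, with pain or guarding marking peritoneal irritation. Its
components, one point each (range 0–6):

| Component | Definition |
|---|---|
| CRP elevation | CRP ≥ 1 mg/dL |
| Heel drop test | positive maneuver |
| Anorexia | reported |
| Nausea or vomiting | reported |
| Shift to left | neutrophils ≥ 75% |
| Elevated WBC | WBC ≥ 10,000/µL |

A total of **≥ 3** flags high risk. The comparator is the Pediatric
Appendicitis Score (PAS), range 0–10, high risk at **≥ 7**, with
double-weighted tenderness items (right-lower-quadrant tenderness and
cough/percussion/hopping tenderness, 2 points each) alongside migration,
anorexia, nausea/vomiting, pyrexia, leukocytosis and left shift (1 point
each). The derivation study that motivates this package does not tabulate
the PAS item weights; we adopt the original Samuel (2002) weighting, which
is the only weighting consistent with the study's reported PAS range (0–10)
and cutoffs (6/7/8). The study analyses fever at ≥ 38.0 °C, so the PAS
pyrexia item uses the same cutpoint. All dichotomizing thresholds are
inclusive (`≥`), exactly as tabulated, and a record missing any component
gets a missing score rather than an imputed one.

## Diagnostic-accuracy statistics

All 2×2 machinery lives in `two_by_two()` / `compute_metrics()`:

* **Sensitivity/specificity CIs** are Clopper–Pearson exact intervals
  (`qbeta` form). This choice reproduces the published intervals — e.g.
  66/84 gives (0.68, 0.87) where Wilson would give (0.69, 0.86).
* **Likelihood-ratio CIs** use the Simel log method:
  `exp(log(LR) ± z·se)` with `se² = 1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)`
  for the positive LR (analogously for the negative LR).
* **PPV/NPV** point estimates are the column proportions `tp/(tp+fp)` and
  `tn/(tn+fn)`. Their intervals are obtained by pushing the LR interval
  through Bayes' theorem at the observed prevalence,
  `PPV = p·PLR / (p·PLR + 1 − p)`. This is the convention of standard
  diagnostic-test calculators and is the only method we found that
  reproduces the published predictive-value intervals (Clopper–Pearson
  differs from them by up to 0.05). When the LR interval is undefined
  (a zero cell), the interval falls back to Clopper–Pearson.
* **Odds ratios** use the Woolf log interval; a zero cell triggers the
  Haldane 0.5 correction of all four cells, flagged in the output.
* **Association p-values**: Pearson chi-square without continuity
  correction, switching to Fisher's exact test when any expected cell is
  below 5. Continuous variables use Welch's t-test. The source study names
  neither rule; ours is recorded in the report metadata, and the test suite
  validates the Fisher branch against a Monte-Carlo permutation oracle.
  Published p-values are matched in direction and significance but not
  asserted at printed precision, because they are not exactly reproducible
  under either the corrected or uncorrected convention.

Undefined metrics (zero denominators) are reported as `NA`, never
fabricated, and every analysis reports the n actually used after per-variable
complete-case exclusion.

## ROC analysis

`empirical_roc()` evaluates one operating point per threshold "score ≥ c"
across the observed score range plus a sentinel, so the staircase always
contains the trivial (1, 0) and (0, 1) points. The AUC is the Mann–Whitney
statistic with tied pairs credited ½ — identical to the trapezoidal area
and, importantly for integer scores where ties are everywhere, the exact
pairwise probability interpretation. The test suite enforces equality with
a brute-force loop over all (positive, negative) pairs on every input.

The variance of the AUC and the paired comparison of two scores on the same
patients use the DeLong–DeLong–Clarke-Pearson structural components
(placement values, computed with midranks): the paired Z-statistic is
`(AUC_a − AUC_b) / sqrt(var_a + var_b − 2·cov_ab)` with two-sided normal
p-values. Identical scores short-circuit to p = 1; a zero-variance
difference with unequal AUCs raises a degeneracy error instead of a bogus
p-value. The implementation is cross-checked in the tests against pROC
(agreement to 1e-10) and against a stratified paired bootstrap.

`youden_cutoff()` maximizes J = sensitivity + specificity − 1 and breaks
ties toward the lowest qualifying cutoff, i.e. toward sensitivity — the
usual screening preference; the source is silent on tie handling.

## The synthetic cohort generator

The study deposits no patient-level data, so `generate_cohort()` emulates
the published *summary* structure: exactly 84 appendicitis (32 complicated,
52 uncomplicated) and 58 non-appendicitis patients by default, every binary
feature drawn at its published group-conditional prevalence, and labs drawn
from the published group-conditional mean ± SD (WBC 13.7 ± 5.3 vs
9.6 ± 3.9 ×10³/µL, and so on), truncated at zero. The CRP ≥ 1 mg/dL
prevalence is not in the published demographics table; it is uniquely
recoverable from the published sensitivity/specificity of that parameter
(52/84 and 22/58) and is flagged as inferred in `printed_counts()`.

Design points:

* **Flag/lab consistency.** A normal with the published mean/SD does not
  reproduce the published flag prevalences exactly (CRP, mean 4.3 ± 9.1,
  is plainly skewed; the normal is a modeling convenience, not a claim
  about the real cohort). By default (`match_flag_prevalence = TRUE`) the
  binary lab flags are drawn directly at the published prevalences —
  marginal fidelity is what downstream checks need — and each lab is then
  drawn from its group's normal *truncated to the region the flag
  implies*, so re-thresholding the labs recovers the flags exactly. The
  two CRP flags are nested bands of a single latent variable, so
  CRP ≥ 5 always implies CRP ≥ 1. Setting the flag to `FALSE` reverses
  the direction: labs are drawn unconditionally and flags derived.
* **Dependence.** Only marginals are published; the joint structure of the
  real cohort is unidentified. Features are coupled through a latent
  Gaussian copula with an exchangeable correlation `rho` (default **0**,
  i.e. independent Bernoulli draws) or a user-supplied correlation matrix
  (validated positive semi-definite). Because thresholding a standard
  normal preserves marginals for any correlation, prevalence fidelity
  holds at every `rho`.
* **Reproducibility.** One master seed spawns deterministic sub-streams
  per group and per variable from a fixed registry, so adding a variable
  to the registry never perturbs the draws of existing ones.
* **Severity gradient.** The study reports mean CHANSE 3.0 ± 1.5 in
  uncomplicated vs 4.6 ± 1.5 in complicated disease.
  `calibrate_severity_shift()` applies one uniform logit shift per
  severity subgroup to the six component prevalences and solves each
  shift by monotone one-dimensional root finding on the closed-form
  expected score (the copula moves the score's variance, never its mean,
  so the expectation is analytic). One shift per subgroup is required:
  the unshifted disease-group expectation is ≈ 3.98, so no single shift
  of the complicated subgroup alone could satisfy both targets. Targets
  equal to the unshifted expectations return zero shifts; targets outside
  (0, 6) raise an error.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: the true inter-feature dependence (real clinical
features are positively correlated; under the default independence the
synthetic scores separate groups somewhat *better* than the published AUCs
of 0.794 vs 0.763), the skewness of CRP and WBC, age/sex structure in
feature prevalence, and any site- or clinician-level effects. The published
score-threshold table and AUC comparison depend on exactly this unpublished
joint distribution, which is why they are checked as properties (oracle
agreement, qualitative ordering) rather than reproduced numerically.

## What is recomputed exactly, and what is not

`reproduce_printed_tables()` recomputes every count-derivable published
cell — odds ratios and Woolf bounds for all binary demographic rows, and
sensitivity/specificity/PPV/NPV/PLR/NLR with intervals for all diagnostic
parameters — and compares at printed precision (±1 unit in the last printed
digit for point estimates; ±0.015 for 2-decimal interval bounds; ±0.02 for
LR bounds, whose method the source does not state). Cells that are
internally inconsistent in the source are reported as skipped with their
reason, never silently passed:

* the fever row (printed sensitivity 0.14 contradicts the same paper's
  fever counts, 35/84 = 0.42; one CI bound also carries an obvious typo);
* the cough/percussion/hopping PLR/NLR cells (printed 1.22/0.56; the row's
  own printed sensitivity/specificity give 1.20/0.58);
* the cough/percussion/hopping OR lower bound (printed 1.056; the printed
  OR and upper bound match Woolf exactly, which implies 0.956);
* the migration sensitivity cell is printed 0.27 while its counts give
  0.262 → 0.26 at two decimals; it passes at the ±1-ulp tolerance and the
  exact-rounding assertion is applied to the seven rows whose counts appear
  verbatim in the demographics table.

## Problem sizes and numerical choices

The test suite and acceptance script choose sizes that make Monte-Carlo
error negligible relative to the tolerance being checked while keeping the
default run in seconds-to-minutes: prevalence recovery at 50,000 patients
per group (3 Monte-Carlo SEs ≈ 0.007), severity calibration at 20,000 per
class (SE of the mean ≈ 0.011 against a ±0.15 band), the bootstrap
comparison of the DeLong variance at n = 200 with 2,000 stratified
resamples, Youden exhaustive search over 500 random cohorts, and
Clopper–Pearson coverage both exactly (binomial summation) and by 10,000
replicates per prevalence point. Truncated normals are sampled by inverse
CDF with the uniform clamped to [1e-12, 1 − 1e-12]; Youden ties use a
1e-12 slack so exact rational ties are honored; all intervals default to
95% two-sided.

## Limitations

This is a reimplementation and stress-test of the published analysis, not a
clinical validation: the score's real-world performance rests on the
original single-center derivation cohort (6–17 years, no external
validation). The generator is a marginal-fidelity emulator; any conclusion
that depends on the joint feature distribution (AUCs, threshold tables,
score correlations) is only qualitatively comparable to the published
values. Continuous-variable odds ratios in the published demographics table
have unstated per-unit scaling and are deliberately not reproduced.
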