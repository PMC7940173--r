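---
title: "Methods: blood-biomarker screening for amyloid PET positivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-biomarker screening for amyloid PET positivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyscreen)
```

## The problem

Disease-modifying therapy for Alzheimer's disease targets the preclinical
stage, when cerebral amyloid-β has accumulated but symptoms have not yet
emerged. Confirming amyloid positivity by PET is expensive and involves
ionising radiation, and CSF sampling is invasive, so neither scales to
population screening. The question this package addresses is quantitative:
if a plasma biomarker — an immunoassay (Simoa) or mass-spectrometry (LC-MS)
measure of amyloid-β species, or phospho-tau181 — is used to *pre-screen*
dementia-free older adults, how many people must be blood-tested, how many
proceed to a confirmatory PET scan, and what does the programme cost relative
to scanning everyone, as functions of the test's operating point and the
population prevalence of PET positivity?

The package implements the full chain: a synthetic cohort generator, a
mixture-model rule for the PET positivity cut-point, logistic concordance
models evaluated by ROC/AUC with paired DeLong comparisons and Youden
cut-points, and the closed-form screening economics.

## The synthetic cohort generator

No participant-level data are distributed, so `generate_cohort()` draws
seeded cohorts whose *summary* structure matches the published
characteristics table of a dementia-free birth-cohort sample (n = 441, 18.6%
amyloid PET-positive, APOE ε4 carriage 57.3% among PET-positives vs 22.0%
among PET-negatives, near-constant age ≈ 70.7 y, 50.6% female).

Per participant, PET status is Bernoulli(prevalence); given status:

* SUVR is Gaussian with status-specific location/scale;
* the APOE ε4 flag is Bernoulli with the status-specific carrier probability;
* each of the seven measured biomarkers (Simoa Aβ40, Aβ42, p-tau181; LC-MS
  Aβ1-38, Aβ1-40, Aβ1-42, Aβ−3-40) is log-normal, with `(meanlog, sdlog)`
  derived from the published per-status median and IQR via
  `lognormal_params_from_median_iqr()`.

A log-normal is symmetric on the log scale, so this construction reproduces
the median and the quartile *ratio* exactly; the individual quartiles are
exact only when the summary is log-symmetric and otherwise agree to within
the summary's log asymmetry (≤ ~2% for these tables). Ratio markers
(Aβ42/Aβ40, and the LC-MS composite defined as the average of the sample
z-scores of the Aβ−3-40/Aβ1-42 and Aβ1-40/Aβ1-42 ratios) are always derived
from the generated peptide levels by `derive_markers()`, never drawn
directly.

**Correlation structure.** Biomarkers are coupled through a Gaussian copula
acting on the latent normal scale (equivalently, a multivariate log-normal
within each PET-status group); the copula leaves every marginal untouched.
The default matrix (`default_biomarker_correlation()`) sets r = 0.6 between
amyloid-β peptides measured on the same platform — the middle of the
reported 0.55–0.70 range for the LC-MS peptides — and the reported weak
cross-platform correlations (0.406 for Aβ40, 0.207 for Aβ42), with p-tau181
independent. This within-platform coupling matters scientifically: the
variance of a ratio of two log-normals is
`s1² + s2² − 2 r s1 s2` on the log scale, so assuming independence (r = 0)
roughly doubles the spread of the Aβ42/Aβ40 ratio within each PET group and
depresses its discriminative performance well below what is observed.
With the default copula the LC-MS ratio's AUC against generated PET status
centres near 0.81, in line with published concordance; under independence it
centres near 0.73. Users wanting conditionally independent biomarkers can
pass the identity matrix.

**SUVR mixture defaults.** The generator's SUVR parameters (PET-negative
N(0.54, 0.030²), PET-positive N(0.70, 0.080²)) are *configuration values*,
not measured population quantities; they are chosen so that the
99th-percentile rule lands near the published cut-point of 0.61
(0.54 + 2.326 × 0.030 = 0.6098).

**What the generator does not emulate.** Biomarkers are conditionally
log-normal given PET status — there is no assay noise model beyond the
log-scale spread, no batch or day effects, no longitudinal drift, and SUVR
is conditionally Gaussian rather than skewed within group. Age carries no
real signal (the source cohort's age range is ~3 years), so the base model's
discrimination comes almost entirely from APOE ε4. Passing tests on these
cohorts demonstrates that the *procedures* behave correctly under the stated
population structure, not that any particular AUC would be attained in new
real data.

## PET status: mixture cut-point

`fit_gmm_1d()` fits a two-component Gaussian mixture to SUVR by EM.
Numerical choices:

* initialisation splits the sample at its median and takes component moments
  from the halves — deterministic given the data; optional seeded random
  restarts are available but default to 0;
* convergence when the absolute log-likelihood change falls below 1e-8, with
  a 1000-iteration cap; the log-likelihood trace is retained and is
  non-decreasing (tested);
* component standard deviations are floored at 1e-6 × the data range to
  prevent collapse; components are reported sorted by mean, so "lower" is
  positional, never label-dependent.

`gmm_cutpoint()` returns the closed-form percentile of the lower
(PET-negative) component, `mean + qnorm(0.99) × sd` by default, and
`classify_pet()` applies the rule with the boundary value counted positive
(SUVR ≥ cut-point). At the default simulation size (441 observations,
~18.6% positive) the overlapping upper component makes individual fits
wander: even the exact maximum-likelihood estimate deviates up to ~0.02 from
the generative truth on some draws. The cut-point itself is much more
stable — across 20 seeded replicates its median absolute error stays below
0.01 SUVR (tested).

## Concordance models

`fit_logistic()` wraps the standard iteratively-reweighted-least-squares
logistic fit and flags complete or quasi-complete separation instead of
returning silently diverging coefficients. Model scores are the fitted
probabilities, so the direction of each biomarker is learned from the data.
For unadjusted single-biomarker models the pipeline additionally reports the
Youden threshold on the original measurement scale (with an explicit
lower-is-positive flag for the Aβ ratios); because the fitted probability is
a monotone function of a single predictor, both scales induce the same
participant partition (tested exactly).

`roc_curve()` uses midpoints between adjacent distinct scores (plus ±∞) as
candidate thresholds and `>=` on the positive side, mirroring the PET rule;
the AUC is the midrank Mann–Whitney statistic with ties counting 1/2, hence
invariant under strictly monotone transforms. `youden_cutpoint()` maximises
J = sensitivity + specificity − 1, breaking ties towards higher sensitivity
and then the smaller threshold; accuracy is
`sens · p + spec · (1 − p)` at the sample prevalence.

`delong_test()` implements the placement-value (structural-component)
estimator of the covariance of two paired AUCs using midranks
(O(n log n)); identical rankings give zero variance, reported as a
degenerate comparison with p = 1. `auc_ci()` uses the same variance
estimator for a normal-approximation interval truncated to [0, 1]. The
published tables do not state the CI method; the DeLong-variance interval
was adopted because it reuses the machinery of the AUC comparisons, and its
width agrees with a participant-level bootstrap within 20% on cohort-sized
fixtures (tested). Inter-assay Pearson correlations are computed after
natural-log transform of both members — except the composite, already a
z-score average, which enters untransformed — with Bonferroni adjustment by
the number of pairs tested.

## Screening economics

Given sensitivity, specificity, prevalence p and a target of n PET-positive
individuals (default n = 100), `solve_screening()` solves the expected
2 × 2 table exactly:

* A = n, A + C = n/sens, NNS = (n/sens)/p;
* B = (1 − spec)(NNS − n/sens), D = spec(NNS − n/sens);
* NPS = A + B, PPV = A/(A+B), NPV = D/(C+D); without screening n/p scans
  are needed.

The percentage of scans saved has the closed form
`(1 − p)(1 − (1 − spec)/sens)`, and
`relative_cost()` computes `(NNS·y + NPS·x)/((n/p)·x)` for PET cost x and
blood-test cost y (setup costs are taken as absorbed into x and y; there is
no amortisation model). All arithmetic is continuous-first; integers are
produced only at reporting time by rounding half away from zero. Published
counts back-calculated from sensitivity/specificity printed to one decimal
can differ from the exact solution by a count or two (e.g. 939 vs a printed
940, 621 vs 623), so a ±2-count reconciliation tolerance is documented and
used in the tests. `prevalence_sweep()` re-solves the design over a 10–50%
prevalence grid in 5% steps; for any informative test PPV rises while NPV
and the scan reduction fall with prevalence — screening buys most in
low-prevalence populations.

## Pipeline and reporting

`run_pipeline()` executes the stages in order — load or simulate, complete-
case filter, derive markers, PET cut-point (mixture rule or a fixed SUVR
value), the nine-model roster (base covariates; Simoa Aβ42/40, Simoa
p-tau181, LC-MS Aβ1-42/1-40, LC-MS composite; each biomarker unadjusted and
with covariates), DeLong comparisons against the base model, Youden
cut-points, screening projections, prevalence sweep and cost curves — and
returns a report bundle serialised as plain CSV plus key-value metadata.
The composite's z-scores are standardised on the complete-case analysis
sample. Report files contain the seed and a configuration hash but no
timestamps, so a given configuration and seed reproduce byte-identical
files. `sweep_pet_cutoff()` re-runs the plasma Youden analysis over a grid
of fixed SUVR cut-points (default 0.57–0.65 by 0.01) and splits the
plasma-vs-PET discordance into plasma-positive/PET-negative and
plasma-negative/PET-positive fractions; the total discordant fraction equals
one minus the plasma classification's accuracy (tested as an identity).

## Problem sizes used by the test-suite

The suite exercises the default cohort size (441) throughout; replicated
properties use 20 seeded cohorts; the pair-counting AUC oracle runs on
50-point instances; the DeLong-vs-bootstrap comparison uses 60 participants
with 10,000 paired bootstrap resamples; the CI-width comparison uses 2,000
resamples; marginal-recovery checks use one 100,000-participant cohort.
These sizes were chosen to keep every stochastic check's Monte-Carlo error
well inside its assertion margin.

## Known limitations

* The generator reproduces marginal summaries and a plausible copula, not
  the full joint distribution of real cohort data; absolute AUCs on
  synthetic cohorts are therefore seed-dependent and only their ordering and
  broad level are meaningful.
* The economics model is an expected-value calculation: no sampling
  variability in the screening counts, no participant attrition between
  blood test and scan, and no setup-cost amortisation.
* The DeLong normal interval can be anti-conservative for AUCs very close
  to 1; the degenerate case is flagged rather than widened.
* Complete-case filtering is the only missing-data strategy, mirroring the
  source analysis; no imputation is provided.
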