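# amyscreen

Blood-biomarker screening for amyloid PET positivity: concordance analysis
and screening-programme economics.

## What this is for

Preclinical Alzheimer's disease — cerebral amyloid-β deposition before
symptoms — can be confirmed by amyloid PET, but PET does not scale to
population screening. Plasma biomarkers (immunoassay and mass-spectrometry
amyloid-β measures, phospho-tau181) are cheap enough to use as a *first*
test, sending only screen-positives to the scanner. `amyscreen` is for
biostatisticians and trial designers who want to quantify that trade-off:

* how well does a blood test (alone, or with age, sex and *APOE* ε4 carrier
  status) reproduce amyloid PET status? — logistic models, ROC/AUC with
  DeLong-variance confidence intervals, paired DeLong AUC comparisons,
  Youden cut-points;
* what does a PET positivity cut-point derived from the SUVR distribution
  itself look like? — a two-component Gaussian mixture with the cut-point at
  the 99th percentile of the lower (PET-negative) component;
* what does screening buy? — the expected 2 × 2 screening design solved in
  closed form for the number needed to screen (NNS), number proceeding to
  scan (NPS), predictive values, scans saved and relative programme cost,
  across prevalence and cost-ratio ranges.

Because participant-level data are not distributable, the package includes a
seeded synthetic-cohort generator matched to published summary statistics
(18.6% PET-positive prevalence, per-status biomarker medians/IQRs, APOE ε4
carriage 57.3% vs 22.0%, bimodal SUVR), so the entire pipeline is testable
end to end.

## The core calculation

For a test with sensitivity *sens* and specificity *spec*, a population
prevalence *p*, and a target of *n* PET-positive individuals, the expected
screening table solves exactly:

    A = n                 (true positives)
    A + C = n / sens      (PET-positives screened)
    NNS = (n / sens) / p  (number needed to screen)
    B = (1 − spec) (NNS − n/sens),  D = spec (NNS − n/sens)
    NPS = A + B,  PPV = A/(A+B),  NPV = D/(C+D)

Without screening, `n / p` scans are needed; the fraction saved is
`(1 − p)(1 − (1 − spec)/sens)`, and a programme with per-unit PET cost *x*
and blood-test cost *y* has relative cost `(NNS·y + NPS·x) / ((n/p)·x)`.

## Worked example

Screening with the LC-MS plasma Aβ1-42/Aβ1-40 ratio at its Youden operating
point (sensitivity 86.6%, specificity 71.9%) in a population with 82/441
PET-positive prevalence:

```r
library(amyscreen)

pr <- solve_screening(test_performance(0.866, 0.719, "LC-MS ratio"),
                      prevalence = 82 / 441)
pr
#> Screening projection (sens 86.6%, spec 71.9%, prevalence 18.6%, target 100):
#>   screen 621, scan 242 (PPV 0.413, NPV 0.959)
#>   296 of 538 scans saved (55.0%)

relative_cost(pr, pet_cost = 1, blood_cost = 0.1)
#> Cost scenario: blood/PET cost ratio 0.100 -> relative programme cost 0.566
```

Read: to find 100 PET-positive individuals you blood-test 621 people and
scan the 242 who screen positive, instead of scanning 538 unscreened people;
41.3% of scanned individuals are truly PET-positive; if the blood test costs
a tenth of a scan the screened programme costs 57% of the unscreened one.

Deriving a PET cut-point from a synthetic cohort's SUVR distribution:

```r
coh <- generate_cohort(cohort_spec(seed = 42))
gmm_cutpoint(fit_gmm_1d(coh$suvr))
#> PET positivity cut-point: SUVR >= 0.6120 (99th percentile of lower component)
```

`run_pipeline(analysis_config(seed = 1))` runs everything — cohort,
cut-point, nine concordance models, Youden cut-points, screening
projections, prevalence sweep (10–50% in 5% steps) and cost curves — and
`write_report_bundle()` serialises the tables as CSV plus run metadata.
A thin command-line front end with `simulate` / `cutpoint` / `concordance` /
`economics` / `run` / `sweep` subcommands is in `inst/cli/amyscreen.R`.

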