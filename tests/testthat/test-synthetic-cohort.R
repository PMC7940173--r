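test_that("log-normal parameters reproduce a median/IQR summary exactly", {
  # LC-MS Abeta42/40 ratio summary in PET-negatives
  p <- lognormal_params_from_median_iqr(0.104, 0.093, 0.116)
  expect_equal(unname(p["meanlog"]), log(0.104), tolerance = 1e-10)
  expect_equal(unname(p["meanlog"]), -2.2634, tolerance = 1e-4)
  expect_equal(unname(p["sdlog"]), 0.16382, tolerance = 1e-4)

  # the implied log-normal matches the median and the quartile ratio
  # exactly; the quartiles themselves agree up to the (small) asymmetry of
  # the summary on the log scale
  q <- qlnorm(c(0.25, 0.5, 0.75), p["meanlog"], p["sdlog"])
  expect_equal(q[2], 0.104, tolerance = 1e-12)
  expect_equal(q[3] / q[1], 0.116 / 0.093, tolerance = 1e-12)
  expect_equal(q, c(0.093, 0.104, 0.116), tolerance = 2e-3)

  # perfectly log-symmetric quartiles are reproduced exactly
  ps <- lognormal_params_from_median_iqr(10, 5, 20)
  expect_equal(qlnorm(c(0.25, 0.5, 0.75), ps["meanlog"], ps["sdlog"]),
               c(5, 10, 20), tolerance = 1e-12)

  # degenerate IQR collapses the scale to zero
  expect_equal(unname(lognormal_params_from_median_iqr(5, 5, 5)["sdlog"]), 0)

  expect_error(lognormal_params_from_median_iqr(1, -1, 2), "invalid summary")
  expect_error(lognormal_params_from_median_iqr(1, 1.5, 2), "invalid summary")
  expect_error(lognormal_params_from_median_iqr(3, 1, 2), "invalid summary")
})

test_that("Monte Carlo draws recover the p-tau181 summary", {
  # PET-negative p-tau181: median 8.5, IQR [6.1, 12.2]
  p <- lognormal_params_from_median_iqr(8.5, 6.1, 12.2)
  set.seed(42)
  draws <- rlnorm(1e6, p["meanlog"], p["sdlog"])
  q <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q, c(6.1, 8.5, 12.2), tolerance = 0.01)
})

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(n_participants = 1), "at least 2")
  expect_error(cohort_spec(prevalence = 0), "strictly in")
  expect_error(cohort_spec(prevalence = 1), "strictly in")
  expect_error(cohort_spec(apoe4_prob_pos = 1.2), "proportions")
  expect_error(cohort_spec(age_sd = -1), "scales")
  bad_cor <- default_biomarker_correlation()
  bad_cor[1, 2] <- bad_cor[2, 1] <- 2
  expect_error(cohort_spec(biomarker_correlation = bad_cor),
               "positive semi-definite")
})

test_that("generation is seed-deterministic and honours tiny cohorts", {
  spec <- small_spec(n = 120, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_cohort(spec, seed = 10)
  expect_false(identical(a$suvr, c2$suvr))

  tiny <- generate_cohort(cohort_spec(n_participants = 2, prevalence = 0.5,
                                      seed = 3))
  expect_equal(nrow(tiny), 2L)
  expect_false(anyDuplicated(tiny$id) > 0)
  expect_true(all(tiny$suvr > 0))
  expect_true(all(tiny[, c("simoa_ab40", "lcms_ab42")] > 0))
})

test_that("a default-parameter cohort matches its target structure", {
  coh <- generate_cohort(cohort_spec(seed = 2024))
  n <- nrow(coh)
  expect_equal(n, 441L)

  # PET-positive fraction within the binomial 95% band around 0.186
  phat <- mean(coh$pet_status == "positive")
  band <- 1.96 * sqrt(0.186 * (1 - 0.186) / n)
  expect_lt(abs(phat - 0.186), band)

  # group-wise medians of key biomarkers within 10% of the target summaries
  params <- default_biomarker_params()
  for (k in c("simoa_ptau181", "lcms_ab42", "lcms_ab40")) {
    for (st in c("negative", "positive")) {
      target <- params$median[params$biomarker == k & params$status == st]
      got <- median(coh[[k]][coh$pet_status == st])
      expect_lt(abs(got - target) / target, 0.10)
    }
  }

  # age truncated to [69, 72]; ages in years around 70.7
  expect_true(all(coh$age >= 69 & coh$age <= 72))
})

test_that("large-sample marginals recover the spec-implied median and IQR", {
  spec <- cohort_spec(n_participants = 1e5, seed = 77)
  coh <- generate_cohort(spec)
  params <- spec$biomarker_params
  for (k in c("simoa_ab42", "lcms_abm3_40")) {
    for (st in c("negative", "positive")) {
      row <- params[params$biomarker == k & params$status == st, ]
      v <- coh[[k]][coh$pet_status == st]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      implied <- qlnorm(c(0.25, 0.5, 0.75), row$meanlog, row$sdlog)
      expect_lt(max(abs(q - implied) / implied), 0.02)
      expect_lt(abs((q[3] - q[1]) - (implied[3] - implied[1])) /
                  (implied[3] - implied[1]), 0.02)
    }
  }
})

test_that("the LC-MS ratio separates generated PET groups plausibly", {
  # broad smoke band: the published concordance is data-dependent, but the
  # generated ratio must discriminate well above chance and below perfection
  coh <- derive_markers(generate_cohort(cohort_spec(seed = 5)))
  roc <- roc_curve(coh$lcms_ab42_ab40,
                   coh$pet_status == "positive", direction = "lower")
  expect_gt(roc$auc, 0.70)
  expect_lt(roc$auc, 0.92)
})

test_that("cohort tables survive a CSV round trip", {
  coh <- generate_cohort(small_spec(n = 50, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  expect_s3_class(back, "cohort_table")
})

test_that("structural invariants are enforced on read", {
  coh <- generate_cohort(small_spec(n = 20, seed = 4))
  coh$id[2] <- coh$id[1]
  expect_error(validate_cohort_table(coh), "unique")
  coh2 <- generate_cohort(small_spec(n = 20, seed = 4))
  coh2$lcms_ab42[3] <- -1
  expect_error(validate_cohort_table(coh2), "strictly positive")
})
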