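test_that("the LC-MS composite is the average of the two ratio z-scores", {
  tab <- data.frame(lcms_ab40 = c(280, 300, 260, 310, 290),
                    lcms_ab42 = c(30, 25, 28, 22, 33),
                    lcms_abm3_40 = c(31, 29, 27, 35, 30))
  got <- lcms_composite(tab)
  # hand computation, independent of the implementation
  r1 <- tab$lcms_abm3_40 / tab$lcms_ab42
  r2 <- tab$lcms_ab40 / tab$lcms_ab42
  expected <- ((r1 - mean(r1)) / sd(r1) + (r2 - mean(r2)) / sd(r2)) / 2
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)
  expect_equal(mean(got), 0, tolerance = 1e-12)

  # a participant whose ratios both equal the sample means scores zero:
  # with unit Abeta1-42 the other peptides ARE the ratios, so pick row 2
  # to sit at the mean of each column
  mtab <- data.frame(lcms_ab42 = rep(1, 3),
                     lcms_ab40 = c(5, 6, 7),
                     lcms_abm3_40 = c(2, 3, 4))
  expect_equal(lcms_composite(mtab)[2], 0, tolerance = 1e-12)

  bad <- tab; bad$lcms_ab42[3] <- 0
  expect_error(lcms_composite(bad), "row\\(s\\) 3")
})

test_that("composite group means are ordered as in the source population", {
  coh <- derive_markers(generate_cohort(cohort_spec(seed = 8)))
  m_pos <- mean(coh$lcms_composite[coh$pet_status == "positive"])
  m_neg <- mean(coh$lcms_composite[coh$pet_status == "negative"])
  expect_gt(m_pos, m_neg) # more cerebral amyloid, higher composite
  expect_equal(mean(coh$lcms_composite), 0, tolerance = 1e-10)
})

test_that("logistic fits match closed-form oracles", {
  # intercept-only: the intercept is the logit of the event fraction
  y <- c(rep(1L, 82), rep(0L, 359))
  m <- fit_logistic(y, data.frame(matrix(nrow = length(y), ncol = 0)))
  expect_equal(unname(m$coefficients[1]), log(82 / 359), tolerance = 1e-8)
  expect_equal(unname(m$coefficients[1]), -1.476, tolerance = 1e-3)

  # one binary predictor: the slope is the log odds ratio of the 2x2 table
  y2 <- c(rep(1, 40), rep(0, 60), rep(1, 15), rep(0, 85))
  x2 <- c(rep(1, 100), rep(0, 100))
  m2 <- fit_logistic(y2, data.frame(x = x2))
  lor <- log((40 * 85) / (60 * 15))
  expect_equal(unname(m2$coefficients["x"]), lor, tolerance = 1e-8)
  expect_true(m2$converged)
})

test_that("complete separation is flagged", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- as.integer(x > 0)
  m <- fit_logistic(y, data.frame(x = x))
  expect_true(m$separation)
  expect_false(m$converged)
})

test_that("degenerate outcomes are rejected", {
  expect_error(fit_logistic(rep(1L, 10), data.frame(x = rnorm(10))),
               "at least one event")
  expect_error(fit_logistic(c(1L, 0L), data.frame(x = c(1, NA))), "missing")
})

test_that("the empirical AUC equals the pair-counting oracle", {
  for (seed in c(1, 2, 3)) {
    d <- make_scores(22, 28, shift = 0.8, seed = seed)
    # inject ties to exercise the 1/2 convention
    d$scores <- round(d$scores, 1)
    roc <- roc_curve(d$scores, d$labels)
    expect_equal(roc$auc, brute_auc(d$scores, d$labels), tolerance = 1e-12)
  }
})

test_that("ROC handles its boundary cases", {
  expect_equal(roc_curve(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  # lower-is-positive orientation mirrors a negated higher-is-positive score
  d <- make_scores(10, 15, seed = 4)
  r_lo <- roc_curve(d$scores, d$labels, direction = "lower")
  r_hi <- roc_curve(-d$scores, d$labels, direction = "higher")
  expect_equal(r_lo$auc, r_hi$auc, tolerance = 1e-12)
  expect_equal(r_lo$sensitivity, r_hi$sensitivity)
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  d <- make_scores(30, 45, shift = 1.2, seed = 6)
  roc <- roc_curve(d$scores, d$labels)
  ref <- pROC::roc(d$labels, d$scores, direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("AUC of fitted probabilities equals AUC of the raw predictor", {
  coh <- derive_markers(generate_cohort(small_spec(n = 300, seed = 12)))
  y <- as.integer(coh$pet_status == "positive")
  m <- fit_logistic(y, coh[, "lcms_ab42_ab40", drop = FALSE])
  auc_prob <- roc_curve(m$fitted, y)$auc
  auc_raw <- roc_curve(coh$lcms_ab42_ab40, y, direction = "lower")$auc
  expect_equal(auc_prob, auc_raw, tolerance = 1e-12)
})

test_that("the probability-scale and biomarker-scale Youden cut-points
           partition participants identically", {
  coh <- derive_markers(generate_cohort(small_spec(n = 300, seed = 13)))
  y <- as.integer(coh$pet_status == "positive")
  m <- fit_logistic(y, coh[, "lcms_ab42_ab40", drop = FALSE])
  cp_prob <- youden_cutpoint(roc_curve(m$fitted, y))
  cp_raw <- youden_cutpoint(roc_curve(coh$lcms_ab42_ab40, y,
                                      direction = "lower"))
  part_prob <- classify_scores(m$fitted, cp_prob)
  part_raw <- classify_scores(coh$lcms_ab42_ab40, cp_raw)
  expect_identical(part_prob, part_raw)
})

test_that("Youden selection matches exhaustive search", {
  set.seed(30)
  scores <- round(rnorm(20), 1)
  labels <- rbinom(20, 1, plogis(scores))
  if (sum(labels) %in% c(0, 20)) labels[1:2] <- c(0L, 1L)
  roc <- roc_curve(scores, labels)
  cp <- youden_cutpoint(roc)
  # brute force over a dense threshold grid (>= rule on the positive side)
  grid <- sort(unique(c(scores - 1e-6, scores + 1e-6, scores)))
  j_grid <- vapply(grid, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, 0)
  expect_equal(cp$youden_j, max(j_grid), tolerance = 1e-12)
  expect_equal(cp$youden_j, cp$sensitivity + cp$specificity - 1)
  p <- mean(labels)
  expect_equal(cp$accuracy, cp$sensitivity * p + cp$specificity * (1 - p))
})

test_that("perfect separation yields a perfect Youden cut-point", {
  cp <- youden_cutpoint(roc_curve(c(1, 2, 8, 9), c(0, 0, 1, 1)))
  expect_equal(cp$youden_j, 1)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
})

test_that("DeLong test degenerates gracefully and respects ranks", {
  d <- make_scores(15, 25, seed = 8)
  same <- delong_test(d$scores, d$scores, d$labels)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_equal(same$auc_a, same$auc_b)

  mono <- delong_test(d$scores, exp(2 * d$scores), d$labels)
  expect_equal(mono$auc_a, mono$auc_b, tolerance = 1e-12)
  expect_equal(mono$p_value, 1)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  n <- 80
  y <- rep(c(1L, 0L), c(30, 50))
  a <- rnorm(n) + y
  b <- 0.6 * a + 0.8 * rnorm(n) + 0.5 * y
  got <- delong_test(a, b, y)
  ra <- pROC::roc(y, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(got$auc_a - got$auc_b,
               as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
               tolerance = 1e-12)
})

test_that("DeLong variance matches a paired bootstrap", {
  set.seed(15)
  n <- 60
  y <- rep(c(1L, 0L), c(20, 40))
  a <- rnorm(n) + 1.2 * y
  b <- 0.7 * a + 0.7 * rnorm(n) + 0.4 * y
  got <- delong_test(a, b, y)
  boot <- replicate(10000, {
    i <- sample.int(n, replace = TRUE)
    while (sum(y[i]) %in% c(0L, n)) i <- sample.int(n, replace = TRUE)
    rank_auc(a[i], y[i]) - rank_auc(b[i], y[i])
  })
  expect_lt(abs(got$var_diff - var(boot)) / var(boot), 0.10)
  expect_gte(got$var_diff, 0)
})

test_that("log-scale Pearson correlations match the textbook formula", {
  set.seed(16)
  tab <- data.frame(a = rlnorm(10, 3, 0.4), b = rlnorm(10, 5, 0.3),
                    lcms_composite = rnorm(10))
  tab$b <- tab$b * tab$a^0.5
  out <- log_pearson_correlations(tab, rbind(c("a", "b"),
                                             c("a", "lcms_composite"),
                                             c("a", "a")))
  # direct sum formula on the log scale
  x <- log(tab$a); yv <- log(tab$b); n <- 10
  r_direct <- (sum(x * yv) - n * mean(x) * mean(yv)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(yv^2) - n * mean(yv)^2))
  expect_equal(out$r[1], r_direct, tolerance = 1e-12)
  # self-correlation is exactly 1; Bonferroni clamps at 1
  expect_equal(out$r[3], 1)
  expect_equal(out$p_bonferroni, pmin(1, out$p_value * 3))
  # the composite row is used untransformed: negative values must be legal
  expect_true(is.finite(out$r[2]))
  bad <- tab; bad$a[4] <- -2
  expect_error(log_pearson_correlations(bad, rbind(c("a", "b"))),
               "non-positive")
})

test_that("adding covariates never lowers the in-sample AUC", {
  coh <- derive_markers(generate_cohort(small_spec(n = 250, seed = 18)))
  y <- as.integer(coh$pet_status == "positive")
  m_small <- fit_logistic(y, coh[, "lcms_ab42_ab40", drop = FALSE])
  m_big <- fit_logistic(y, coh[, c("lcms_ab42_ab40", "age", "sex",
                                   "apoe4_carrier")])
  expect_gte(roc_curve(m_big$fitted, y)$auc + 1e-10,
             roc_curve(m_small$fitted, y)$auc)
})
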