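#' Log-normal parameters reproducing a given median and interquartile range
#'
#' Converts a median and quartile summary of a positively skewed biomarker into
#' the `(meanlog, sdlog)` parameters of the log-normal distribution that has
#' exactly that median and interquartile range. Used to turn published
#' "median \[IQR\]" rows into a generative model for synthetic cohorts.
#'
#' The median of a log-normal is `exp(meanlog)`, so `meanlog = log(median)`.
#' On the log scale the quartiles sit at `meanlog +/- z_0.75 * sdlog` with
#' `z_0.75 = qnorm(0.75) ~ 0.674490`, giving
#' `sdlog = (log(q3) - log(q1)) / (2 * z_0.75)`. The resulting distribution
#' has exactly the given median and quartile ratio `q3/q1`; the individual
#' quartiles (and hence the IQR) are reproduced exactly when the summary is
#' log-symmetric (`median = sqrt(q1 * q3)`) and to within the summary's
#' log-scale asymmetry otherwise — at most a couple of percent for the
#' biomarker tables used here.
#'
#' @param median,q1,q3 Positive scalars with `0 < q1 <= median <= q3`
#'   (concentration units, e.g. pg/ml).
#' @return Named numeric vector `c(meanlog, sdlog)` (log units).
#' @examples
#' lognormal_params_from_median_iqr(0.104, 0.093, 0.116)
#' @export
lognormal_params_from_median_iqr <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))))
    stop("invalid summary: median and quartiles must be finite", call. = FALSE)
  if (q1 <= 0)
    stop("invalid summary: quartiles must be positive", call. = FALSE)
  if (q1 > median || median > q3)
    stop("invalid summary: need q1 <= median <= q3", call. = FALSE)
  c(meanlog = log(median),
    sdlog   = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Default per-status biomarker summaries
#'
#' Median and quartiles of each plasma biomarker by amyloid PET status used to
#' parameterise the synthetic cohort generator: Simoa (single molecule array)
#' amyloid-beta 40 and 42 and p-tau181, and LC-MS (immunoprecipitation mass
#' spectrometry) amyloid-beta 1-38, 1-40, 1-42 and the N-terminally extended
#' amyloid-beta -3-40 (APP669-711). All values in pg/ml.
#'
#' @return Data frame with columns `biomarker`, `status`, `median`, `q1`, `q3`.
#' @export
default_biomarker_params <- function() {
  tab <- rbind(
    c("simoa_ab40",    "negative", 289,   255,   319),
    c("simoa_ab40",    "positive", 285,   257,   328),
    c("simoa_ab42",    "negative", 19.9,  17.1,  22.6),
    c("simoa_ab42",    "positive", 18.1,  15.5,  22.9),
    c("simoa_ptau181", "negative", 8.5,   6.1,   12.2),
    c("simoa_ptau181", "positive", 12.8,  9.2,   16.0),
    c("lcms_ab38",     "negative", 24.8,  21.6,  27.9),
    c("lcms_ab38",     "positive", 24.5,  21.6,  28.7),
    c("lcms_ab40",     "negative", 284,   255,   314),
    c("lcms_ab40",     "positive", 285,   260,   311),
    c("lcms_ab42",     "negative", 29.6,  24.9,  34.2),
    c("lcms_ab42",     "positive", 23.7,  20.3,  27.2),
    c("lcms_abm3_40",  "negative", 30.1,  24.4,  35.7),
    c("lcms_abm3_40",  "positive", 29.9,  24.4,  34.9))
  out <- data.frame(biomarker = tab[, 1], status = tab[, 2],
                    median = as.numeric(tab[, 3]), q1 = as.numeric(tab[, 4]),
                    q3 = as.numeric(tab[, 5]), stringsAsFactors = FALSE)
  out
}

#' Default latent correlation between biomarkers
#'
#' Correlation matrix of the Gaussian copula used to draw biomarkers jointly
#' within each PET-status group. Amyloid-beta peptides measured on the same
#' platform are moderately correlated (r = 0.6, the middle of the reported
#' 0.55--0.70 range for the LC-MS peptides); the matching peptides across
#' platforms carry the reported weak cross-platform correlations (0.406 for
#' amyloid-beta 40, 0.207 for amyloid-beta 42); p-tau181 is left independent.
#' Because the copula acts on the latent normal scale, marginal medians and
#' IQRs are unchanged by any choice of matrix.
#'
#' @return 7 x 7 correlation matrix with dimnames equal to the biomarker names.
#' @export
default_biomarker_correlation <- function() {
  nm <- biomarker_names()
  r <- diag(length(nm))
  dimnames(r) <- list(nm, nm)
  set_r <- function(r, a, b, v) { r[a, b] <- v; r[b, a] <- v; r }
  r <- set_r(r, "simoa_ab40", "simoa_ab42", 0.6)
  lcms <- c("lcms_ab38", "lcms_ab40", "lcms_ab42", "lcms_abm3_40")
  for (i in 1:3) for (j in (i + 1):4) r <- set_r(r, lcms[i], lcms[j], 0.6)
  r <- set_r(r, "simoa_ab40", "lcms_ab40", 0.406)
  r <- set_r(r, "simoa_ab42", "lcms_ab42", 0.207)
  r
}

biomarker_names <- function() {
  c("simoa_ab40", "simoa_ab42", "simoa_ptau181",
    "lcms_ab38", "lcms_ab40", "lcms_ab42", "lcms_abm3_40")
}

#' Specify a synthetic cohort
#'
#' Bundles the population quantities that define a synthetic dementia-free
#' cohort: size, amyloid PET positivity prevalence, demographic distributions,
#' the per-status SUVR mixture, and per-status log-normal biomarker parameters
#' derived from median/IQR summaries.
#'
#' The SUVR mixture defaults (PET-negative mean 0.54, sd 0.030; PET-positive
#' mean 0.70, sd 0.080) are generator configuration chosen so that the
#' 99th-percentile rule lands near a cut-point of 0.61; they are not measured
#' population values.
#'
#' @param n_participants Number of participants (>= 2).
#' @param prevalence Proportion amyloid PET-positive, strictly in (0, 1).
#' @param age_mean,age_sd Mean and SD of age at blood sampling (years).
#' @param age_range Truncation bounds for age (years).
#' @param frac_female Proportion female.
#' @param apoe4_prob_pos,apoe4_prob_neg APOE e4 carrier probability given
#'   PET-positive / PET-negative status.
#' @param suvr_mix List with elements `negative` and `positive`, each
#'   `c(mean, sd)` on the SUVR scale.
#' @param biomarker_params Data frame as [default_biomarker_params()].
#' @param biomarker_correlation Copula correlation matrix as
#'   [default_biomarker_correlation()]; identity gives conditionally
#'   independent biomarkers.
#' @param seed Integer RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 441L,
                        prevalence = 82 / 441,
                        age_mean = 70.7, age_sd = 0.7,
                        age_range = c(69, 72),
                        frac_female = 0.506,
                        apoe4_prob_pos = 0.573,
                        apoe4_prob_neg = 0.220,
                        suvr_mix = list(negative = c(mean = 0.54, sd = 0.030),
                                        positive = c(mean = 0.70, sd = 0.080)),
                        biomarker_params = default_biomarker_params(),
                        biomarker_correlation = default_biomarker_correlation(),
                        seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 2L)
    stop("n_participants must be at least 2", call. = FALSE)
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  props <- c(frac_female = frac_female, apoe4_prob_pos = apoe4_prob_pos,
             apoe4_prob_neg = apoe4_prob_neg)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (age_sd <= 0 || any(vapply(suvr_mix, function(p) p[["sd"]], 0) <= 0))
    stop("scales must be positive", call. = FALSE)
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
  needed <- c("biomarker", "status", "median", "q1", "q3")
  if (!all(needed %in% names(biomarker_params)))
    stop("biomarker_params must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  nm <- sort(unique(biomarker_params$biomarker))
  if (!identical(sort(rownames(biomarker_correlation)), nm) &&
      !is.null(rownames(biomarker_correlation)))
    stop("biomarker_correlation dimnames must match the biomarkers",
         call. = FALSE)
  ev <- eigen(biomarker_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("biomarker_correlation must be positive semi-definite", call. = FALSE)
  # derive log-normal parameters once, validating every summary row
  pars <- mapply(lognormal_params_from_median_iqr,
                 biomarker_params$median, biomarker_params$q1,
                 biomarker_params$q3)
  biomarker_params$meanlog <- pars["meanlog", ]
  biomarker_params$sdlog <- pars["sdlog", ]
  structure(list(n_participants = n_participants, prevalence = prevalence,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 frac_female = frac_female,
                 apoe4_prob_pos = apoe4_prob_pos,
                 apoe4_prob_neg = apoe4_prob_neg,
                 suvr_mix = suvr_mix,
                 biomarker_params = biomarker_params,
                 biomarker_correlation = biomarker_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n = %d, PET-positive prevalence = %.3f, seed = %d\n",
              x$n_participants, x$prevalence, x$seed))
  cat(sprintf("  SUVR mixture: neg N(%.2f, %.3f), pos N(%.2f, %.3f)\n",
              x$suvr_mix$negative[["mean"]], x$suvr_mix$negative[["sd"]],
              x$suvr_mix$positive[["mean"]], x$suvr_mix$positive[["sd"]]))
  cat(sprintf("  %d biomarkers x 2 PET-status groups (log-normal marginals)\n",
              length(unique(x$biomarker_params$biomarker))))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a per-participant table with the joint structure the downstream
#' analysis assumes: amyloid PET status is Bernoulli(prevalence); SUVR comes
#' from the status-specific Gaussian; the APOE e4 carrier flag is Bernoulli
#' with the status-specific probability; age is truncated normal and sex
#' Bernoulli; biomarkers are drawn from a Gaussian copula with status-specific
#' log-normal marginals. The same spec and seed give a bit-identical table.
#'
#' Ratio markers (amyloid-beta 42/40 etc.) are never drawn directly; derive
#' them from the generated peptide levels with [derive_markers()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return Data frame of class `cohort_table` with one row per participant:
#'   `id`, `age`, `sex` (`"female"`/`"male"`), `apoe4_carrier` (0/1), `suvr`,
#'   the seven biomarker columns (pg/ml), and `pet_status`
#'   (`"negative"`/`"positive"`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_participants = 100, seed = 7))
#' table(coh$pet_status)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "cohort_spec"))
    stop("spec must be a cohort_spec", call. = FALSE)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  n <- spec$n_participants
  set.seed(seed)

  positive <- stats::rbinom(n, 1L, spec$prevalence) == 1L
  mu_s <- ifelse(positive, spec$suvr_mix$positive[["mean"]],
                 spec$suvr_mix$negative[["mean"]])
  sd_s <- ifelse(positive, spec$suvr_mix$positive[["sd"]],
                 spec$suvr_mix$negative[["sd"]])
  suvr <- stats::rnorm(n, mu_s, sd_s)

  # inverse-CDF truncated normal keeps the draw count deterministic
  lo <- stats::pnorm(spec$age_range[1], spec$age_mean, spec$age_sd)
  hi <- stats::pnorm(spec$age_range[2], spec$age_mean, spec$age_sd)
  age <- stats::qnorm(lo + stats::runif(n) * (hi - lo),
                      spec$age_mean, spec$age_sd)

  sex <- ifelse(stats::rbinom(n, 1L, spec$frac_female) == 1L,
                "female", "male")
  p_apoe <- ifelse(positive, spec$apoe4_prob_pos, spec$apoe4_prob_neg)
  apoe4 <- stats::rbinom(n, 1L, p_apoe)

  nm <- biomarker_names_from_params(spec$biomarker_params)
  r <- spec$biomarker_correlation
  if (!is.null(rownames(r))) r <- r[nm, nm, drop = FALSE]
  z <- matrix(stats::rnorm(n * length(nm)), n, length(nm)) %*% chol_psd(r)
  colnames(z) <- nm
  bm <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (k in nm) {
    for (st in c("negative", "positive")) {
      row <- spec$biomarker_params[spec$biomarker_params$biomarker == k &
                                     spec$biomarker_params$status == st, ]
      if (nrow(row) != 1L)
        stop("biomarker_params needs exactly one row per biomarker and status",
             call. = FALSE)
      idx <- if (st == "positive") positive else !positive
      bm[idx, k] <- exp(row$meanlog + row$sdlog * z[idx, k])
    }
  }

  out <- data.frame(id = sprintf("P%04d", seq_len(n)),
                    age = age, sex = sex, apoe4_carrier = apoe4,
                    suvr = suvr, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(bm))
  out$pet_status <- ifelse(positive, "positive", "negative")
  class(out) <- c("cohort_table", "data.frame")
  validate_cohort_table(out)
  out
}

biomarker_names_from_params <- function(params) {
  nm <- unique(params$biomarker)
  ord <- biomarker_names()
  c(ord[ord %in% nm], setdiff(nm, ord))
}

# Cholesky factor tolerating semi-definite matrices (e.g. perfectly
# correlated markers in a user-supplied copula)
chol_psd <- function(r) {
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(r, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Validate a cohort table
#'
#' Checks the structural invariants an analysis-ready cohort must satisfy:
#' required columns present, unique ids, positive SUVR and concentrations.
#' Missing values are permitted here (they are removed by the pipeline's
#' complete-case filter).
#'
#' @param x A data frame.
#' @return `x`, invisibly, with class `cohort_table`.
#' @export
validate_cohort_table <- function(x) {
  required <- c("id", "age", "sex", "apoe4_carrier", "suvr", biomarker_names())
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$id))
    stop("cohort table ids must be unique", call. = FALSE)
  num <- c("suvr", biomarker_names())
  for (k in num) {
    v <- x[[k]]
    if (any(!is.na(v) & v <= 0))
      stop("cohort table column ", k, " must be strictly positive",
           call. = FALSE)
  }
  if (!inherits(x, "cohort_table")) class(x) <- c("cohort_table", class(x))
  invisible(x)
}

#' Write / read a cohort table as comma-separated text
#'
#' The on-disk format is plain CSV with a fixed header (`id, age, sex,
#' apoe4_carrier, suvr`, the seven biomarker columns, and optionally
#' `pet_status`); missing values are encoded as empty fields.
#'
#' @param x A `cohort_table`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated `cohort_table`.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- intersect(c("age", "suvr", biomarker_names()), names(x))
  for (k in num) x[[k]] <- as.numeric(x[[k]])
  validate_cohort_table(x)
  class(x) <- c("cohort_table", "data.frame")
  x
}
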