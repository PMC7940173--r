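#' Fit a two-component Gaussian mixture to one-dimensional SUVR values
#'
#' Expectation-maximisation fit of `w1 N(m1, s1^2) + w2 N(m2, s2^2)` to a
#' vector of standardized uptake value ratios (SUVR). The lower-mean
#' component is interpreted as the amyloid PET-negative population and feeds
#' the positivity cut-point rule in [gmm_cutpoint()].
#'
#' Initialisation splits the sample at its median and takes component moments
#' from the two halves, so the fit is deterministic given the data; `restarts`
#' random restarts (seeded) can be requested to guard against local optima,
#' with the best log-likelihood retained. Component standard deviations are
#' floored at `1e-6 * diff(range(values))` to prevent collapse onto a single
#' observation. Components are always reported sorted by mean.
#'
#' @param values Numeric vector of at least 4 finite, not all identical, SUVR
#'   values.
#' @param tol Convergence tolerance on the absolute log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param restarts Number of additional random initialisations (default 0).
#' @param seed RNG seed used only when `restarts > 0`.
#' @return Object of class `gmm1d`: `weights`, `means`, `sds` (sorted by
#'   mean), `loglik`, `loglik_trace`, `n_iter`, `converged`, `lower_index`,
#'   and the `n x 2` responsibility matrix `responsibilities`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(400, 0.54, 0.03), rnorm(100, 0.70, 0.08))
#' fit <- fit_gmm_1d(x)
#' fit$means
#' @export
fit_gmm_1d <- function(values, tol = 1e-8, max_iter = 1000L,
                       restarts = 0L, seed = 0L) {
  x <- as.numeric(values)
  if (any(!is.finite(x)))
    stop("values must all be finite", call. = FALSE)
  if (length(x) < 4L)
    stop("need at least 4 values to fit a two-component mixture",
         call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate data: all values identical", call. = FALSE)
  sd_floor <- 1e-6 * diff(range(x))

  median_init <- function() {
    lower <- x[x <= stats::median(x)]
    upper <- x[x > stats::median(x)]
    if (!length(upper)) { # heavy ties at the median
      upper <- x[x >= stats::median(x)]
      lower <- x[x < stats::median(x)]
    }
    list(w = c(length(lower), length(upper)) / length(x),
         mu = c(mean(lower), mean(upper)),
         sd = pmax(c(stats::sd(lower), stats::sd(upper)), sd_floor,
                   na.rm = TRUE))
  }
  random_init <- function() {
    mu <- sort(sample(x, 2L))
    list(w = c(0.5, 0.5), mu = mu,
         sd = pmax(rep(stats::sd(x) / 2, 2L), sd_floor))
  }

  inits <- list(median_init())
  if (restarts > 0L) {
    set.seed(seed)
    inits <- c(inits, replicate(restarts, random_init(), simplify = FALSE))
  }

  best <- NULL
  for (init in inits) {
    fit <- em_gmm_1d(x, init, tol, max_iter, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)
  best
}

em_gmm_1d <- function(x, init, tol, max_iter, sd_floor) {
  w <- init$w; mu <- init$mu; s <- init$sd
  n <- length(x)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E step (log-sum-exp for numerical stability)
    lp <- cbind(log(w[1]) + stats::dnorm(x, mu[1], s[1], log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], s[2], log = TRUE))
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    new_loglik <- sum(lse)
    resp <- exp(lp - lse)
    # M step
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    s <- pmax(s, sd_floor)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && abs(new_loglik - loglik) < tol) {
      converged <- TRUE
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  ord <- order(mu)
  resp <- resp[, ord, drop = FALSE]
  structure(list(weights = w[ord], means = mu[ord], sds = s[ord],
                 loglik = loglik, loglik_trace = trace, n_iter = it,
                 converged = converged, lower_index = 1L,
                 responsibilities = resp, n = n),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("Two-component Gaussian mixture (1-D)\n")
  cat(sprintf("  component 1 (lower): weight %.3f, mean %.4f, sd %.4f\n",
              x$weights[1], x$means[1], x$sds[1]))
  cat(sprintf("  component 2 (upper): weight %.3f, mean %.4f, sd %.4f\n",
              x$weights[2], x$means[2], x$sds[2]))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Amyloid PET positivity cut-point from a fitted SUVR mixture
#'
#' The cut-point is the given percentile (default the 99th) of the lower,
#' amyloid PET-negative, Gaussian component: `mean_lower +
#' qnorm(percentile) * sd_lower` (`qnorm(0.99) = 2.326348`). Exact closed
#' form; no sampling.
#'
#' @param fit A `gmm1d` fit from [fit_gmm_1d()].
#' @param percentile Proportion strictly in (0, 1); default 0.99.
#' @param allow_unconverged Proceed even if the EM fit did not converge.
#' @return Object of class `pet_cutpoint`: `suvr_threshold`, `percentile`,
#'   and the source `fit`.
#' @export
gmm_cutpoint <- function(fit, percentile = 0.99, allow_unconverged = FALSE) {
  if (!inherits(fit, "gmm1d")) stop("fit must be a gmm1d", call. = FALSE)
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 1)
    stop("percentile must lie strictly in (0, 1)", call. = FALSE)
  if (!fit$converged && !allow_unconverged)
    stop("mixture fit did not converge; pass allow_unconverged = TRUE to ",
         "override", call. = FALSE)
  i <- fit$lower_index
  thr <- fit$means[i] + stats::qnorm(percentile) * fit$sds[i]
  structure(list(suvr_threshold = thr, percentile = percentile,
                 source_fit = fit),
            class = "pet_cutpoint")
}

#' @export
print.pet_cutpoint <- function(x, ...) {
  cat(sprintf(
    "PET positivity cut-point: SUVR >= %.4f (%.0fth percentile of lower component)\n",
    x$suvr_threshold, 100 * x$percentile))
  invisible(x)
}

#' Classify amyloid PET status from SUVR
#'
#' A scan is PET-positive when its SUVR is at or above the cut-point
#' (the boundary value itself is positive) and PET-negative below it.
#'
#' @param suvr Numeric vector of finite SUVR values.
#' @param cutpoint A `pet_cutpoint` or a single numeric threshold.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify_pet <- function(suvr, cutpoint) {
  thr <- if (inherits(cutpoint, "pet_cutpoint")) cutpoint$suvr_threshold
         else as.numeric(cutpoint)
  if (!is.finite(thr) || length(thr) != 1L)
    stop("cutpoint must be a single finite threshold", call. = FALSE)
  if (any(!is.finite(suvr)))
    stop("suvr values must be finite", call. = FALSE)
  ifelse(suvr >= thr, "positive", "negative")
}
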