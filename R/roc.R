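#' Empirical ROC curve
#'
#' Receiver operating characteristic of a score against a binary amyloid PET
#' status. Candidate thresholds are the midpoints between adjacent distinct
#' sorted scores plus the two infinite endpoints; classification at a
#' threshold uses `>=` on the positive side (mirroring the SUVR rule). The
#' AUC is computed by the midrank (Mann-Whitney) formula, with ties
#' contributing 1/2, and is therefore invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric score per participant.
#' @param labels Binary status (logical, 0/1, or `"positive"`/`"negative"`).
#' @param direction `"higher"` if larger scores indicate PET positivity
#'   (fitted probabilities, p-tau181, composite), `"lower"` if smaller scores
#'   do (amyloid-beta 42/40 ratios). With `"lower"`, a threshold `t`
#'   classifies `score <= t` as positive.
#' @return Object of class `roc_curve`: `thresholds` (original score scale),
#'   `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`, `direction`, plus
#'   the scores and 0/1 labels (used by [delong_test()] and [auc_ci()]).
#' @examples
#' roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' roc$auc
#' @export
roc_curve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  y <- as_binary_outcome(labels)
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(y))
  if (anyNA(scores) || anyNA(y))
    stop("missing values in scores or labels", call. = FALSE)
  n_pos <- sum(y); n_neg <- sum(1 - y)
  if (n_pos < 1L || n_neg < 1L)
    stop("ROC undefined: both classes must be present", call. = FALSE)

  s <- if (direction == "lower") -scores else scores
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  s_pos <- s[y == 1L]; s_neg <- s[y == 0L]
  sens <- vapply(thr, function(t) mean(s_pos >= t), 0)
  spec <- vapply(thr, function(t) mean(s_neg < t), 0)

  r <- rank(s) # midranks
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  structure(list(thresholds = if (direction == "lower") -thr else thr,
                 sensitivity = sens, specificity = spec, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, direction = direction,
                 scores = scores, labels = y),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC %.3f (%d positive, %d negative; %s scores positive)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' Youden's index cut-point
#'
#' Selects the threshold maximising `J = sensitivity + specificity - 1` from
#' an empirical ROC curve. Accuracy is evaluated at the sample prevalence,
#' `accuracy = sens * p + spec * (1 - p)`. Ties in J are resolved towards the
#' highest sensitivity, then the smallest threshold, so the result is
#' deterministic.
#'
#' @param roc A [roc_curve()].
#' @return Object of class `cutpoint_result`: `threshold` (score scale),
#'   `sensitivity`, `specificity`, `accuracy`, `youden_j`, `direction`.
#' @export
youden_cutpoint <- function(roc) {
  if (!inherits(roc, "roc_curve")) stop("roc must be a roc_curve", call. = FALSE)
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    best <- best[roc$sensitivity[best] >= max(roc$sensitivity[best]) - 1e-12]
    if (length(best) > 1L) best <- best[which.min(roc$thresholds[best])]
  }
  best <- best[1L]
  p <- roc$n_pos / (roc$n_pos + roc$n_neg)
  sens <- roc$sensitivity[best]; spec <- roc$specificity[best]
  structure(list(threshold = roc$thresholds[best],
                 sensitivity = sens, specificity = spec,
                 accuracy = sens * p + spec * (1 - p),
                 youden_j = sens + spec - 1,
                 direction = roc$direction),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  rule <- if (x$direction == "lower") "<=" else ">="
  cat(sprintf("Youden cut-point: score %s %.4g\n", rule, x$threshold))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f, J = %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$youden_j))
  invisible(x)
}

#' Classify participants at a score threshold
#'
#' Applies a [youden_cutpoint()] (or an explicit threshold and direction) to
#' a vector of scores, using `>=` on the positive side for higher-is-positive
#' scores and `<=` for lower-is-positive scores.
#'
#' @param scores Numeric scores.
#' @param cutpoint A `cutpoint_result`, or a single numeric threshold.
#' @param direction Used only when `cutpoint` is numeric.
#' @return Integer vector: 1 = screen positive, 0 = screen negative.
#' @export
classify_scores <- function(scores, cutpoint,
                            direction = c("higher", "lower")) {
  if (inherits(cutpoint, "cutpoint_result")) {
    thr <- cutpoint$threshold
    direction <- cutpoint$direction
  } else {
    thr <- as.numeric(cutpoint)
    direction <- match.arg(direction)
  }
  if (direction == "lower") as.integer(scores <= thr)
  else as.integer(scores >= thr)
}

# Midrank placement values: V10 for positives, V01 for negatives.
# mean(V10) = mean(V01) = AUC (Mann-Whitney with ties counted 1/2).
placement_values <- function(scores, y) {
  pos <- y == 1L
  m <- sum(pos); n <- sum(!pos)
  r_all <- rank(scores)
  v10 <- (r_all[pos] - rank(scores[pos])) / n
  v01 <- 1 - (r_all[!pos] - rank(scores[!pos])) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong test for two paired AUCs
#'
#' Nonparametric comparison of the areas under two correlated ROC curves
#' measured on the same participants, using the placement-value (structural
#' component) estimator of the covariance of the two AUCs. The statistic
#' `z = (auc_a - auc_b) / sqrt(var)` is referred to the standard normal for a
#' two-sided p-value. Placement values are computed with midranks, so the
#' test runs in O(n log n) and handles ties.
#'
#' If the two scores rank the participants identically the variance of the
#' difference is zero; the comparison is then degenerate and the p-value is
#' reported as 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired numeric scores for the same participants,
#'   both oriented so that higher values indicate positivity.
#' @param labels Binary status shared by the two scores.
#' @return Object of class `delong_test`: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_outcome(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  if (sum(y) < 1L || sum(1 - y) < 1L)
    stop("both classes must be present", call. = FALSE)
  pa <- placement_values(as.numeric(scores_a), y)
  pb <- placement_values(as.numeric(scores_b), y)
  var_diff <- stats::var(pa$v10 - pb$v10) / pa$m +
    stats::var(pa$v01 - pb$v01) / pa$n
  d <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff < 1e-14) {
    z <- if (abs(d) < 1e-14) 0 else sign(d) * Inf
    return(structure(list(auc_a = pa$auc, auc_b = pb$auc,
                          var_diff = max(var_diff, 0), z = z,
                          p_value = if (abs(d) < 1e-14) 1 else 0,
                          degenerate = TRUE),
                     class = "delong_test"))
  }
  z <- d / sqrt(var_diff)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 degenerate = FALSE),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p_value,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' DeLong-variance confidence interval for an AUC
#'
#' Normal-approximation interval `auc +/- z * sqrt(var)`, where the AUC
#' variance is the placement-value (DeLong) estimator
#' `var(V10)/n_pos + var(V01)/n_neg`, truncated to \[0, 1\]. A degenerate
#' (zero) variance collapses the interval to the point estimate, with a flag.
#'
#' @param roc A [roc_curve()].
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, auc, upper)` with attributes `var` and
#'   `degenerate`.
#' @export
auc_ci <- function(roc, level = 0.95) {
  if (!inherits(roc, "roc_curve")) stop("roc must be a roc_curve", call. = FALSE)
  s <- if (roc$direction == "lower") -roc$scores else roc$scores
  p <- placement_values(s, roc$labels)
  v <- stats::var(p$v10) / p$m + stats::var(p$v01) / p$n
  degenerate <- !is.finite(v) || v < 1e-14
  half <- if (degenerate) 0 else stats::qnorm(1 - (1 - level) / 2) * sqrt(v)
  out <- c(lower = max(0, roc$auc - half), auc = roc$auc,
           upper = min(1, roc$auc + half))
  attr(out, "var") <- if (degenerate) 0 else v
  attr(out, "degenerate") <- degenerate
  out
}
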