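#' Logistic regression of amyloid PET status on blood biomarkers
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary PET status on one or more predictors. The
#' fitted probabilities are the model scores fed into ROC analysis, so the
#' direction of any biomarker (e.g. lower amyloid-beta 42/40 being the
#' at-risk direction) is learned rather than assumed.
#'
#' Complete or quasi-complete separation is detected from the usual
#' fitted-probabilities-of-0-or-1 diagnostic together with exploding
#' coefficients; a separated model is flagged and marked unconverged rather
#' than silently returned.
#'
#' @param outcome Binary outcome: logical, 0/1, or `"positive"`/`"negative"`.
#' @param predictors Data frame (or named list) of predictor columns; factors
#'   and character columns are expanded by the usual model-matrix rules.
#' @return Object of class `logistic_model`: `coefficients`, `converged`,
#'   `separation`, `n_obs`, `fitted` (probabilities), `predictors` (names),
#'   and the underlying `glm` object as `fit`.
#' @export
fit_logistic <- function(outcome, predictors) {
  y <- as_binary_outcome(outcome)
  predictors <- as.data.frame(predictors, stringsAsFactors = FALSE)
  if (nrow(predictors) != length(y))
    stop("outcome and predictors must have the same length", call. = FALSE)
  if (anyNA(predictors) || anyNA(y))
    stop("missing values in outcome or predictors", call. = FALSE)
  if (sum(y) < 1L || sum(1 - y) < 1L)
    stop("need at least one event and one non-event", call. = FALSE)
  dat <- cbind(data.frame(.outcome = y), predictors)
  form <- if (ncol(predictors)) .outcome ~ . else .outcome ~ 1
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  separation <- sep_warn && max(abs(coefs[-1]), 0) > 10
  converged <- fit$converged && !separation
  structure(list(coefficients = coefs,
                 converged = converged,
                 separation = separation,
                 n_obs = length(y),
                 fitted = as.numeric(stats::fitted(fit)),
                 predictors = names(predictors),
                 fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model (%d obs): %s\n", x$n_obs,
              paste(x$predictors, collapse = " + ")))
  print(round(x$coefficients, 4))
  if (x$separation) cat("  WARNING: separation detected; fit unreliable\n")
  invisible(x)
}

as_binary_outcome <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.factor(outcome)) outcome <- as.character(outcome)
  if (is.character(outcome)) {
    if (!all(outcome %in% c("positive", "negative")))
      stop('character outcome must be "positive"/"negative"', call. = FALSE)
    return(as.integer(outcome == "positive"))
  }
  if (is.numeric(outcome)) {
    if (!all(outcome %in% c(0, 1)))
      stop("numeric outcome must be 0/1", call. = FALSE)
    return(as.integer(outcome))
  }
  stop("unsupported outcome type", call. = FALSE)
}
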