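#' Screening test performance
#'
#' A sensitivity/specificity pair with a label, as read off a Youden
#' cut-point or a published table. A test is flagged informative when
#' `sensitivity + specificity > 1`.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @param label Model name.
#' @return Object of class `test_performance`.
#' @export
test_performance <- function(sensitivity, specificity, label = "") {
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1 ||
      !is.finite(specificity) || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 label = label,
                 informative = sensitivity + specificity > 1),
            class = "test_performance")
}

as_test_performance <- function(perf) {
  if (inherits(perf, "test_performance")) return(perf)
  if (inherits(perf, "cutpoint_result"))
    return(test_performance(perf$sensitivity, perf$specificity))
  if (is.list(perf) && !is.null(perf$sensitivity) &&
      !is.null(perf$specificity))
    return(test_performance(perf$sensitivity, perf$specificity,
                            if (is.null(perf$label)) "" else perf$label))
  stop("perf must provide sensitivity and specificity", call. = FALSE)
}

# round half away from zero (so 0.5 -> 1, not banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Solve the screening 2 x 2 design
#'
#' Given a blood test's sensitivity and specificity, the population
#' prevalence of amyloid PET positivity, and a target number of PET-positive
#' individuals to identify, solves the expected 2 x 2 table in closed form:
#'
#' * `A = n_target` true positives; `A + C = n / sens` PET-positives screened;
#' * number needed to screen `NNS = (n / sens) / p`;
#' * `B = (1 - spec) * (NNS - n/sens)` false positives,
#'   `D = spec * (NNS - n/sens)` true negatives;
#' * number proceeding to scan `NPS = A + B`; `PPV = A / (A + B)`;
#'   `NPV = D / (C + D)`; without screening `n / p` scans would be needed.
#'
#' All quantities are solved continuously; integer values for reporting are
#' produced by rounding half away from zero and kept alongside the exact
#' solution. Published counts derived from sensitivity/specificity rounded to
#' one decimal can differ from the exact back-calculation by a count or two.
#'
#' @param perf A [test_performance()], a [youden_cutpoint()] result, or any
#'   list with `sensitivity` and `specificity`.
#' @param prevalence Proportion PET-positive, strictly in (0, 1).
#' @param n_target Number of PET-positive individuals sought (default 100).
#' @return Object of class `screening_projection` with fields `sensitivity`,
#'   `specificity`, `prevalence`, `n_target`, cells `A`, `B`, `C`, `D`,
#'   `nns`, `nps`, `ppv`, `npv`, `baseline_scans`, `scans_saved`,
#'   `pct_scans_saved`, and a `rounded` list of the integer-reported values.
#' @examples
#' solve_screening(test_performance(0.573, 0.783), prevalence = 82 / 441)
#' @export
solve_screening <- function(perf, prevalence, n_target = 100) {
  perf <- as_test_performance(perf)
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  if (perf$sensitivity == 0)
    stop("infeasible design: a test with zero sensitivity can never reach ",
         "the target", call. = FALSE)
  if (n_target < 1) stop("n_target must be at least 1", call. = FALSE)
  sens <- perf$sensitivity; spec <- perf$specificity
  a <- n_target
  apc <- n_target / sens           # PET-positives screened (A + C)
  nns <- apc / prevalence
  cc <- apc - a
  b <- (1 - spec) * (nns - apc)
  d <- spec * (nns - apc)
  nps <- a + b
  baseline <- n_target / prevalence
  saved <- baseline - nps
  structure(list(sensitivity = sens, specificity = spec,
                 prevalence = prevalence, n_target = n_target,
                 label = perf$label,
                 A = a, B = b, C = cc, D = d,
                 nns = nns, nps = nps,
                 ppv = a / (a + b), npv = d / (cc + d),
                 baseline_scans = baseline, scans_saved = saved,
                 pct_scans_saved = 100 * saved / baseline,
                 rounded = lapply(list(nns = nns, nps = nps,
                                       baseline_scans = baseline,
                                       scans_saved = saved),
                                  round_half_away)),
            class = "screening_projection")
}

#' @export
print.screening_projection <- function(x, ...) {
  cat(sprintf(
    "Screening projection (sens %.1f%%, spec %.1f%%, prevalence %.1f%%, target %g):\n",
    100 * x$sensitivity, 100 * x$specificity, 100 * x$prevalence, x$n_target))
  cat(sprintf("  screen %g, scan %g (PPV %.3f, NPV %.3f)\n",
              x$rounded$nns, x$rounded$nps, x$ppv, x$npv))
  cat(sprintf("  %g of %g scans saved (%.1f%%)\n", x$rounded$scans_saved,
              x$rounded$baseline_scans, x$pct_scans_saved))
  invisible(x)
}

#' Scans saved by blood-test pre-screening
#'
#' Summarises the scan reduction of a screening design relative to scanning
#' unscreened individuals until the target is reached
#' (`baseline = n_target / prevalence` scans), and optionally relative to a
#' reference screening design (negative percentages mean the design saves
#' fewer scans than the reference). The percentage saved also has the closed
#' form `(1 - p) * (1 - (1 - spec) / sens)`.
#'
#' @param projection A [solve_screening()] result.
#' @param reference Optional second projection to compare against.
#' @return List: `baseline_scans`, `scans_saved`, `pct_scans_saved`, and
#'   `pct_vs_reference` when a reference is supplied.
#' @export
scans_saved <- function(projection, reference = NULL) {
  stopifnot(inherits(projection, "screening_projection"))
  out <- list(baseline_scans = projection$baseline_scans,
              scans_saved = projection$scans_saved,
              pct_scans_saved = projection$pct_scans_saved)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "screening_projection"))
    out$pct_vs_reference <-
      100 * (projection$scans_saved - reference$scans_saved) /
      reference$scans_saved
  }
  out
}

#' Relative cost of a blood-prescreened programme
#'
#' Total cost of blood-testing `NNS` individuals and scanning the `NPS` who
#' screen positive, divided by the cost of scanning `n_target / p` unscreened
#' individuals: `(NNS * y + NPS * x) / ((n/p) * x)` for PET scan cost `x` and
#' blood test cost `y`. Values below 1 mean the screened programme is
#' cheaper. Setup costs are assumed absorbed into the per-unit costs.
#'
#' @param projection A [solve_screening()] result.
#' @param pet_cost Cost of one PET scan (`x > 0`), any currency unit.
#' @param blood_cost Cost of one blood test (`y >= 0`), same unit.
#' @return Object of class `cost_scenario`: `pet_cost`, `blood_cost`,
#'   `cost_ratio` (`y/x`) and `relative_cost`.
#' @export
relative_cost <- function(projection, pet_cost, blood_cost) {
  stopifnot(inherits(projection, "screening_projection"))
  if (!is.finite(pet_cost) || pet_cost <= 0)
    stop("pet_cost must be positive", call. = FALSE)
  if (!is.finite(blood_cost) || blood_cost < 0)
    stop("blood_cost must be non-negative", call. = FALSE)
  rel <- (projection$nns * blood_cost + projection$nps * pet_cost) /
    (projection$baseline_scans * pet_cost)
  structure(list(pet_cost = pet_cost, blood_cost = blood_cost,
                 cost_ratio = blood_cost / pet_cost, relative_cost = rel),
            class = "cost_scenario")
}

#' @export
print.cost_scenario <- function(x, ...) {
  cat(sprintf(
    "Cost scenario: blood/PET cost ratio %.3f -> relative programme cost %.3f\n",
    x$cost_ratio, x$relative_cost))
  invisible(x)
}

#' Screening projections across a prevalence range
#'
#' Re-solves the screening design at each prevalence on a grid (default
#' 10--50% in 5% steps) and tabulates NNS, NPS, predictive values and scan
#' reduction. For any informative test (`sens + spec > 1`) PPV increases and
#' NPV and the percentage of scans saved decrease as prevalence rises.
#'
#' @param perf As in [solve_screening()].
#' @param p_min,p_max,step Prevalence grid, `0 < p_min <= p_max < 1`,
#'   `step > 0`.
#' @param n_target Target number of PET-positive individuals.
#' @return Data frame with one row per prevalence: `prevalence`, `nns`,
#'   `nps`, `ppv`, `npv`, `scans_saved`, `pct_scans_saved`.
#' @export
prevalence_sweep <- function(perf, p_min = 0.10, p_max = 0.50, step = 0.05,
                             n_target = 100) {
  if (!is.finite(p_min) || !is.finite(p_max) || p_min <= 0 || p_max >= 1 ||
      p_min > p_max)
    stop("need 0 < p_min <= p_max < 1", call. = FALSE)
  if (!is.finite(step) || step <= 0)
    stop("step must be positive", call. = FALSE)
  ps <- seq(p_min, p_max, by = step)
  rows <- lapply(ps, function(p) {
    pr <- solve_screening(perf, p, n_target)
    data.frame(prevalence = p, nns = pr$nns, nps = pr$nps, ppv = pr$ppv,
               npv = pr$npv, scans_saved = pr$scans_saved,
               pct_scans_saved = pr$pct_scans_saved)
  })
  do.call(rbind, rows)
}
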