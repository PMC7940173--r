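#' LC-MS plasma amyloid-beta composite
#'
#' The composite is the average of the sample z-scores of the
#' amyloid-beta -3-40 / amyloid-beta 1-42 and amyloid-beta 1-40 /
#' amyloid-beta 1-42 ratios. Both ratios rise as plasma amyloid-beta 1-42
#' falls, so higher composite values indicate more cerebral amyloid.
#' Standardisation uses the mean and SD of the supplied analysis sample, so
#' the composite has sample mean 0 by construction.
#'
#' @param table A `cohort_table` (or data frame) with positive `lcms_ab40`,
#'   `lcms_ab42` and `lcms_abm3_40` columns.
#' @return Numeric vector of per-participant composite values, with the
#'   standardisation constants attached as attribute `scaling`
#'   (`list(center, scale)` for the two ratios).
#' @export
lcms_composite <- function(table) {
  for (k in c("lcms_ab40", "lcms_ab42", "lcms_abm3_40"))
    if (is.null(table[[k]]))
      stop("table must contain column ", k, call. = FALSE)
  bad <- which(!is.finite(table$lcms_ab42) | table$lcms_ab42 <= 0)
  if (length(bad))
    stop("invalid record: non-positive lcms_ab42 in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  r1 <- table$lcms_abm3_40 / table$lcms_ab42
  r2 <- table$lcms_ab40 / table$lcms_ab42
  center <- c(r1 = mean(r1), r2 = mean(r2))
  scale <- c(r1 = stats::sd(r1), r2 = stats::sd(r2))
  z1 <- (r1 - center["r1"]) / scale["r1"]
  z2 <- (r2 - center["r2"]) / scale["r2"]
  out <- as.numeric((z1 + z2) / 2)
  attr(out, "scaling") <- list(center = center, scale = scale)
  out
}

#' Derive ratio and composite markers from peptide levels
#'
#' Appends the analysis-scale markers to a cohort table: the Simoa and LC-MS
#' amyloid-beta 42/40 ratios and the LC-MS composite. Ratios are always
#' computed from the measured peptide columns so that ratio consistency is
#' structural, never drawn or stored independently.
#'
#' @param table A `cohort_table`.
#' @return The table with columns `simoa_ab42_ab40`, `lcms_ab42_ab40` and
#'   `lcms_composite` appended (existing columns of those names are
#'   recomputed).
#' @export
derive_markers <- function(table) {
  table$simoa_ab42_ab40 <- table$simoa_ab42 / table$simoa_ab40
  table$lcms_ab42_ab40 <- table$lcms_ab42 / table$lcms_ab40
  comp <- lcms_composite(table)
  attributes(comp) <- NULL
  table$lcms_composite <- comp
  table
}

#' Pearson correlations between log-transformed biomarkers
#'
#' Plasma biomarker concentrations are positively skewed, so both members of
#' each pair are natural-log transformed before computing the Pearson
#' correlation — except the LC-MS composite, which is already a z-score
#' average and is used untransformed. P-values come from the usual t
#' reference distribution and are Bonferroni-adjusted by the number of pairs
#' tested.
#'
#' @param table Data frame holding the biomarker columns.
#' @param pairs Two-column character matrix or data frame of column-name
#'   pairs to correlate.
#' @return Data frame with one row per pair: `var_a`, `var_b`, `n`, `r`,
#'   `p_value`, `p_bonferroni`.
#' @export
log_pearson_correlations <- function(table, pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("pairs must have two columns", call. = FALSE)
  n_pairs <- nrow(pairs)
  maybe_log <- function(name) {
    v <- table[[name]]
    if (is.null(v)) stop("no column named ", name, call. = FALSE)
    if (identical(name, "lcms_composite")) return(v)
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("invalid record: non-positive value of ", name, " in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    log(v)
  }
  rows <- lapply(seq_len(n_pairs), function(i) {
    x <- maybe_log(pairs[i, 1]); y <- maybe_log(pairs[i, 2])
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L)
      stop("need at least 3 complete pairs for ", pairs[i, 1], " vs ",
           pairs[i, 2], call. = FALSE)
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var_a = pairs[i, 1], var_b = pairs[i, 2], n = sum(ok),
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * n_pairs)
  out
}
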