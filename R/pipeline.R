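#' Analysis configuration
#'
#' Collects everything the end-to-end pipeline needs: the input source
#' (exactly one of a cohort CSV path or a simulation [cohort_spec()]), the
#' PET cut-point mode, the model roster, the prevalence-sweep grid, the
#' blood/PET cost-ratio grid, and the seed.
#'
#' @param input Path to a cohort CSV ([read_cohort()] format), or `NULL` to
#'   simulate.
#' @param spec A [cohort_spec()] used when `input` is `NULL`; defaults to the
#'   package's Table-matched cohort with the given seed.
#' @param cutpoint_mode `"gmm"` (mixture-model cut-point from the data) or
#'   `"fixed"`.
#' @param fixed_cutpoint SUVR threshold used when `cutpoint_mode = "fixed"`.
#' @param percentile Percentile of the lower Gaussian for the GMM cut-point.
#' @param roster Model roster; defaults to [default_roster()].
#' @param n_target Target number of PET-positive individuals for the
#'   screening projections.
#' @param sweep_min,sweep_max,sweep_step Prevalence-sweep grid.
#' @param cost_ratios Blood-test/PET-scan cost ratios (y/x) for the cost
#'   curves.
#' @param seed Integer seed governing simulation.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes the
#'   report files there.
#' @param verbose Emit per-stage progress messages.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, spec = NULL,
                            cutpoint_mode = c("gmm", "fixed"),
                            fixed_cutpoint = NULL, percentile = 0.99,
                            roster = default_roster(), n_target = 100,
                            sweep_min = 0.10, sweep_max = 0.50,
                            sweep_step = 0.05,
                            cost_ratios = seq(0.05, 0.50, by = 0.05),
                            seed = 1L, out_dir = NULL, verbose = FALSE) {
  cutpoint_mode <- match.arg(cutpoint_mode)
  if (!is.null(input) && !is.null(spec))
    stop("supply exactly one input source: a file path or a cohort_spec",
         call. = FALSE)
  if (is.null(input) && is.null(spec)) spec <- cohort_spec(seed = seed)
  if (cutpoint_mode == "fixed") {
    if (is.null(fixed_cutpoint) || !is.finite(fixed_cutpoint) ||
        fixed_cutpoint <= 0)
      stop("fixed cut-point mode needs a positive fixed_cutpoint",
           call. = FALSE)
  }
  if (!length(roster)) stop("model roster must be non-empty", call. = FALSE)
  structure(list(input = input, spec = spec, cutpoint_mode = cutpoint_mode,
                 fixed_cutpoint = fixed_cutpoint, percentile = percentile,
                 roster = roster, n_target = n_target,
                 sweep_min = sweep_min, sweep_max = sweep_max,
                 sweep_step = sweep_step, cost_ratios = cost_ratios,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "analysis_config")
}

#' Default model roster
#'
#' The nine concordance/screening models: a base model (age, sex, APOE e4
#' carrier status), the two best biomarkers from each assay platform
#' unadjusted (Simoa amyloid-beta 42/40 ratio, Simoa p-tau181, LC-MS
#' amyloid-beta 1-42/1-40 ratio, LC-MS composite), and the same four
#' biomarkers with the base covariates added. `direction` records which way
#' the raw marker points for biomarker-scale ROC reporting.
#'
#' @return List of model definitions (`name`, `label`, `marker`, `adjusted`,
#'   `direction`).
#' @export
default_roster <- function() {
  markers <- list(
    list(name = "simoa_ab42_ab40", label = "Simoa plasma Aβ42/Aβ40",
         marker = "simoa_ab42_ab40", direction = "lower"),
    list(name = "simoa_ptau181", label = "Simoa plasma p-tau181",
         marker = "simoa_ptau181", direction = "higher"),
    list(name = "lcms_ab42_ab40", label = "LC-MS plasma Aβ1-42/Aβ1-40",
         marker = "lcms_ab42_ab40", direction = "lower"),
    list(name = "lcms_composite", label = "LC-MS plasma composite",
         marker = "lcms_composite", direction = "higher"))
  base <- list(list(name = "base", label = "Age + sex + APOE ε4",
                    marker = NULL, adjusted = TRUE, direction = NA_character_))
  unadj <- lapply(markers, function(m) c(m, list(adjusted = FALSE)))
  adj <- lapply(markers, function(m) {
    m$name <- paste0(m$name, "_adj")
    m$label <- paste0(m$label, " + age + sex + APOE ε4")
    c(m, list(adjusted = TRUE))
  })
  c(base, unadj, adj)
}

analysis_columns <- function() {
  c("id", "age", "sex", "apoe4_carrier", "suvr", biomarker_names())
}

#' Run the end-to-end screening analysis
#'
#' Executes the full pipeline: load or simulate the cohort, apply the
#' complete-case filter, derive ratio/composite markers, fix the amyloid PET
#' cut-point (Gaussian-mixture rule or a supplied value), fit the roster of
#' logistic concordance models, evaluate each by ROC/AUC with DeLong
#' comparison against the base model, select Youden cut-points, and project
#' the screening economics (2 x 2 solution, prevalence sweep, cost curves).
#' Deterministic given the config seed.
#'
#' @param config An [analysis_config()].
#' @return Object of class `report_bundle`: `cohort_summary`, `concordance`,
#'   `screening`, `sweep`, `cost` data frames, the per-model fit objects in
#'   `models`, the cut-point in `cutpoint`, the analysis cohort in `cohort`,
#'   and run `metadata` (seed, config hash, sizes). If `config$out_dir` is
#'   set the report files are also written there.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(analysis_config(spec = cohort_spec(seed = 11)))
#' bundle$concordance
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config"))
    stop("config must be an analysis_config", call. = FALSE)
  say <- function(...) if (config$verbose) message("[amyscreen] ", ...)

  # --- stage: input -------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$spec, seed = config$seed)
  }, error = function(e) stop("stage input: ", conditionMessage(e),
                              call. = FALSE))
  n_total <- nrow(cohort)
  say("input: ", n_total, " participants")

  # --- stage: complete-case filter ---------------------------------------
  keep <- stats::complete.cases(cohort[, analysis_columns()])
  cohort <- cohort[keep, , drop = FALSE]
  if (!nrow(cohort))
    stop("stage filter: no complete cases in the analysis set", call. = FALSE)
  say("complete cases: ", nrow(cohort))
  cohort <- derive_markers(cohort)

  # --- stage: PET cut-point ----------------------------------------------
  if (config$cutpoint_mode == "gmm") {
    fit <- tryCatch(fit_gmm_1d(cohort$suvr),
                    error = function(e) stop("stage pet_cutpoint: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    cutpoint <- gmm_cutpoint(fit, config$percentile,
                             allow_unconverged = TRUE)
  } else {
    cutpoint <- structure(list(suvr_threshold = config$fixed_cutpoint,
                               percentile = NA_real_, source_fit = NULL),
                          class = "pet_cutpoint")
  }
  cohort$pet_status <- classify_pet(cohort$suvr, cutpoint)
  n_pos <- sum(cohort$pet_status == "positive")
  if (n_pos == 0L || n_pos == nrow(cohort))
    stop("stage pet_cutpoint: cut-point yields a single PET class",
         call. = FALSE)
  prevalence <- n_pos / nrow(cohort)
  say(sprintf("PET cut-point %.4f: %d/%d positive (%.1f%%)",
              cutpoint$suvr_threshold, n_pos, nrow(cohort),
              100 * prevalence))

  # --- stage: concordance models -----------------------------------------
  y <- as.integer(cohort$pet_status == "positive")
  covars <- cohort[, c("age", "sex", "apoe4_carrier")]
  models <- lapply(config$roster, function(def) {
    preds <- if (is.null(def$marker)) covars
             else if (def$adjusted) cbind(cohort[, def$marker, drop = FALSE],
                                          covars)
             else cohort[, def$marker, drop = FALSE]
    model <- fit_logistic(y, preds)
    roc <- roc_curve(model$fitted, y, direction = "higher")
    cp <- youden_cutpoint(roc)
    marker_cp <- NULL
    if (!is.null(def$marker) && !def$adjusted) {
      marker_roc <- roc_curve(cohort[[def$marker]], y,
                              direction = def$direction)
      marker_cp <- youden_cutpoint(marker_roc)
    }
    list(def = def, model = model, roc = roc, cutpoint = cp,
         marker_cutpoint = marker_cp)
  })
  names(models) <- vapply(config$roster, `[[`, "", "name")
  if (!"base" %in% names(models))
    say("no base model in roster; DeLong comparisons omitted")
  say("fitted ", length(models), " models")

  # --- stage: tables ------------------------------------------------------
  base_fitted <- if ("base" %in% names(models))
    models[["base"]]$model$fitted else NULL
  concordance <- do.call(rbind, lapply(models, function(m) {
    ci <- auc_ci(m$roc)
    dl_z <- dl_p <- NA_real_
    if (!is.null(base_fitted) && m$def$name != "base") {
      dl <- delong_test(m$model$fitted, base_fitted, y)
      dl_z <- dl$z; dl_p <- dl$p_value
    }
    data.frame(model = m$def$name, label = m$def$label, auc = m$roc$auc,
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               delong_z_vs_base = dl_z, delong_p_vs_base = dl_p,
               stringsAsFactors = FALSE)
  }))
  rownames(concordance) <- NULL

  base_proj <- if ("base" %in% names(models))
    solve_screening(models[["base"]]$cutpoint, prevalence, config$n_target)
  else NULL
  screening <- do.call(rbind, lapply(models, function(m) {
    cp <- m$cutpoint
    proj <- solve_screening(cp, prevalence, config$n_target)
    sv <- scans_saved(proj, reference = base_proj)
    data.frame(model = m$def$name,
               sensitivity_pct = 100 * cp$sensitivity,
               specificity_pct = 100 * cp$specificity,
               accuracy_pct = 100 * cp$accuracy,
               marker_threshold = if (is.null(m$marker_cutpoint)) NA_real_
                                  else m$marker_cutpoint$threshold,
               nns = proj$rounded$nns, nps = proj$rounded$nps,
               nns_exact = proj$nns, nps_exact = proj$nps,
               ppv = proj$ppv, npv = proj$npv,
               scans_saved = proj$rounded$scans_saved,
               pct_scans_saved = proj$pct_scans_saved,
               pct_vs_base = if (is.null(base_proj) || m$def$name == "base")
                 NA_real_ else sv$pct_vs_reference,
               stringsAsFactors = FALSE)
  }))
  rownames(screening) <- NULL

  sweep <- do.call(rbind, lapply(models, function(m) {
    tab <- prevalence_sweep(m$cutpoint, config$sweep_min, config$sweep_max,
                            config$sweep_step, config$n_target)
    cbind(model = m$def$name, tab, stringsAsFactors = FALSE)
  }))
  rownames(sweep) <- NULL

  cost <- do.call(rbind, lapply(models, function(m) {
    proj <- solve_screening(m$cutpoint, prevalence, config$n_target)
    do.call(rbind, lapply(config$cost_ratios, function(r) {
      data.frame(model = m$def$name, cost_ratio = r,
                 relative_cost = relative_cost(proj, 1, r)$relative_cost,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(cost) <- NULL

  bundle <- structure(
    list(cohort_summary = summarize_cohort(cohort),
         concordance = concordance, screening = screening,
         sweep = sweep, cost = cost,
         models = models, cutpoint = cutpoint, cohort = cohort,
         metadata = list(seed = config$seed,
                         config_hash = config_hash(config),
                         n_total = n_total, n_analysis = nrow(cohort),
                         n_pet_positive = n_pos, prevalence = prevalence,
                         suvr_cutpoint = cutpoint$suvr_threshold,
                         cutpoint_mode = config$cutpoint_mode,
                         n_target = config$n_target,
                         package_version =
                           as.character(utils::packageVersion("amyscreen")))),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  md <- x$metadata
  cat("amyscreen report bundle\n")
  cat(sprintf("  %d analysed (%d PET-positive, prevalence %.1f%%), SUVR cut-point %.4f\n",
              md$n_analysis, md$n_pet_positive, 100 * md$prevalence,
              md$suvr_cutpoint))
  cat(sprintf("  %d models; seed %d, config hash %s\n",
              nrow(x$concordance), md$seed, md$config_hash))
  invisible(x)
}

#' Descriptive cohort summary by PET status
#'
#' Summary table in the usual cohort-characteristics shape: per PET-status
#' group and overall, mean (SD) for approximately normal variables (age,
#' composite), median \[IQR\] for skewed ones (SUVR, concentrations), and
#' percentages for binary variables.
#'
#' @param cohort A cohort table with `pet_status` and derived markers.
#' @return Data frame with columns `characteristic`, `negative`, `positive`,
#'   `overall` (formatted strings).
#' @export
summarize_cohort <- function(cohort) {
  grp <- list(negative = cohort[cohort$pet_status == "negative", ],
              positive = cohort[cohort$pet_status == "positive", ],
              overall = cohort)
  mean_sd <- function(v) sprintf("%.3g (%.3g)", mean(v), stats::sd(v))
  med_iqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3g [%.3g, %.3g]", q[2], q[1], q[3])
  }
  pct <- function(v) sprintf("%.1f", 100 * mean(v))
  rows <- list(
    c("n", vapply(grp, function(g) as.character(nrow(g)), "")),
    c("Age, years, mean (SD)", vapply(grp, function(g) mean_sd(g$age), "")),
    c("Sex, % female",
      vapply(grp, function(g) pct(g$sex == "female"), "")),
    c("APOE e4, % carrier",
      vapply(grp, function(g) pct(g$apoe4_carrier == 1), "")),
    c("SUVR, median [IQR]", vapply(grp, function(g) med_iqr(g$suvr), "")))
  for (k in biomarker_names())
    rows <- c(rows, list(c(paste0(k, ", pg/ml, median [IQR]"),
                           vapply(grp, function(g) med_iqr(g[[k]]), ""))))
  for (k in c("simoa_ab42_ab40", "lcms_ab42_ab40"))
    rows <- c(rows, list(c(paste0(k, ", median [IQR]"),
                           vapply(grp, function(g) med_iqr(g[[k]]), ""))))
  rows <- c(rows, list(c("lcms_composite, mean (SD)",
                         vapply(grp, function(g) mean_sd(g$lcms_composite),
                                ""))))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("characteristic", "negative", "positive", "overall")
  out
}

#' Write a report bundle as plain-text files
#'
#' Serialises every table of a [run_pipeline()] bundle as CSV plus a
#' machine-readable `metadata.txt` in `key=value` form. Output contains no
#' timestamps, so the same configuration and seed reproduce byte-identical
#' files.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("cohort_summary", "concordance", "screening", "sweep",
               "cost")) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  md <- bundle$metadata
  lines <- vapply(names(md), function(k)
    paste0(k, "=", format(md[[k]], digits = 15)), "")
  writeLines(lines, file.path(dir, "metadata.txt"))
  invisible(dir)
}

# stable hash of the configuration (md5 of its deparsed form)
config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  x$verbose <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Sensitivity of the plasma cut-point to the PET SUVR threshold
#'
#' Re-runs the plasma concordance analysis over a grid of fixed SUVR
#' cut-points (default 0.57--0.65 in 0.01 steps): at each cut-point the
#' cohort is reclassified, the Youden plasma cut-point recomputed, and the
#' plasma-vs-PET discordance split into plasma-positive/PET-negative and
#' plasma-negative/PET-positive fractions. The total discordant fraction
#' equals one minus the accuracy of the plasma classification against that
#' PET definition. A cut-point yielding a single PET class is flagged and
#' its metrics left missing.
#'
#' @param cohort A cohort table (derived markers are added if absent).
#' @param marker Plasma marker column to evaluate.
#' @param direction Direction of the raw marker (`"lower"` for amyloid-beta
#'   ratios).
#' @param cut_min,cut_max,step SUVR cut-point grid.
#' @return Data frame, one row per cut-point: `suvr_cutoff`, `n_pos`,
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`, `accuracy`,
#'   `frac_discordant`, `frac_plasma_pos_pet_neg`, `frac_plasma_neg_pet_pos`,
#'   `skipped`.
#' @export
sweep_pet_cutoff <- function(cohort, marker = "lcms_ab42_ab40",
                             direction = c("lower", "higher"),
                             cut_min = 0.57, cut_max = 0.65, step = 0.01) {
  direction <- match.arg(direction)
  if (!is.finite(cut_min) || !is.finite(cut_max) || cut_min > cut_max ||
      step <= 0)
    stop("invalid cut-point range", call. = FALSE)
  if (cut_min < min(cohort$suvr) || cut_max > max(cohort$suvr))
    stop("cut-point range must lie within the observed SUVR span",
         call. = FALSE)
  if (is.null(cohort[[marker]])) cohort <- derive_markers(cohort)
  cuts <- seq(cut_min, cut_max, by = step)
  rows <- lapply(cuts, function(ct) {
    pet <- as.integer(cohort$suvr >= ct)
    n_pos <- sum(pet)
    if (n_pos == 0L || n_pos == length(pet)) {
      return(data.frame(suvr_cutoff = ct, n_pos = n_pos,
                        threshold = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, youden_j = NA_real_,
                        accuracy = NA_real_, frac_discordant = NA_real_,
                        frac_plasma_pos_pet_neg = NA_real_,
                        frac_plasma_neg_pet_pos = NA_real_, skipped = TRUE))
    }
    roc <- roc_curve(cohort[[marker]], pet, direction = direction)
    cp <- youden_cutpoint(roc)
    plasma <- classify_scores(cohort[[marker]], cp)
    disc <- plasma != pet
    data.frame(suvr_cutoff = ct, n_pos = n_pos, threshold = cp$threshold,
               sensitivity = cp$sensitivity, specificity = cp$specificity,
               youden_j = cp$youden_j, accuracy = cp$accuracy,
               frac_discordant = mean(disc),
               frac_plasma_pos_pet_neg =
                 if (any(disc)) mean(plasma[disc] == 1L) else 0,
               frac_plasma_neg_pet_pos =
                 if (any(disc)) mean(plasma[disc] == 0L) else 0,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
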