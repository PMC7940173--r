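#' Read an analysis configuration from a flat key-value file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Unknown keys are rejected. Cohort keys
#' (`n_participants`, `prevalence`, `frac_female`, `apoe4_prob_pos`,
#' `apoe4_prob_neg`) override the defaults of the simulation [cohort_spec()];
#' the remaining keys map directly onto [analysis_config()] arguments
#' (`input`, `cutpoint_mode`, `fixed_cutpoint`, `percentile`, `n_target`,
#' `sweep_min`, `sweep_max`, `sweep_step`, `cost_ratios` as a comma-separated
#' list, `seed`, `out_dir`).
#'
#' @param path Path to the config file.
#' @param seed Optional seed overriding the file's `seed` key.
#' @return An [analysis_config()].
#' @export
read_config <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad))
    stop("unparseable config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  if (anyDuplicated(keys))
    stop("duplicate config keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  names(vals) <- keys

  cohort_keys <- c("n_participants", "prevalence", "frac_female",
                   "apoe4_prob_pos", "apoe4_prob_neg")
  config_num <- c("fixed_cutpoint", "percentile", "n_target", "sweep_min",
                  "sweep_max", "sweep_step")
  known <- c(cohort_keys, config_num,
             "input", "cutpoint_mode", "cost_ratios", "seed", "out_dir")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  num <- function(k) if (k %in% keys) as.numeric(vals[[k]]) else NULL
  chr <- function(k) if (k %in% keys) vals[[k]] else NULL

  the_seed <- if (!is.null(seed)) as.integer(seed)
              else if ("seed" %in% keys) as.integer(vals[["seed"]]) else 1L

  args <- list(seed = the_seed)
  if (!is.null(chr("input"))) {
    args$input <- chr("input")
  } else {
    spec_args <- list(seed = the_seed)
    for (k in cohort_keys) if (!is.null(num(k))) spec_args[[k]] <- num(k)
    args$spec <- do.call(cohort_spec, spec_args)
  }
  if (!is.null(chr("cutpoint_mode"))) args$cutpoint_mode <- chr("cutpoint_mode")
  for (k in config_num) if (!is.null(num(k))) args[[k]] <- num(k)
  if (!is.null(chr("cost_ratios")))
    args$cost_ratios <- as.numeric(strsplit(chr("cost_ratios"), ",")[[1]])
  if (!is.null(chr("out_dir"))) args$out_dir <- chr("out_dir")
  do.call(analysis_config, args)
}
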