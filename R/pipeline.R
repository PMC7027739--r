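# End-to-end orchestration: raw tables -> physiology and stoichiometry ->
# plot join -> mixed-model tests, correlations and piecewise SEM.

read_input <- function(x, name) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      md_stop(sprintf("input file for `%s` not found: %s", name, x),
              "schema_error")
    }
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) {
    md_stop(sprintf("`%s` must be a data frame or a CSV path", name),
            "schema_error")
  }
  x
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on raw tables (data frames or CSV paths):
#' per-sample physiology and biomass/necromass, aggregation to plot level,
#' join with the plot table, sequential likelihood-ratio tests for every
#' response, the block-corrected Pearson correlation matrix, and the
#' piecewise SEM. When `out_dir` is given, writes `physiology.csv`,
#' `biomass_necromass.csv`, `lmm_tests.csv`, `correlations.csv`,
#' `sem_fit.json` and a run `manifest.json`.
#'
#' @param plots Plot table (`plot_id`, `block`, `psr_sown`, `pfgr`,
#'   functional-group flags, and plot covariates such as `soc`, `root_c`).
#' @param incubation,isotope,cfe,dna,aminosugars Raw measurement tables;
#'   see [compute_physiology()] and [compute_biomass_necromass()].
#' @param model Path model for the SEM stage, default
#'   [default_path_model()].
#' @param order Term order for the sequential tests, see
#'   [sequential_lr_tests()].
#' @param mode `"lenient"` or `"strict"` measurement policy.
#' @param lmm_responses Responses to test; defaults to every derived
#'   variable present.
#' @param cor_variables Variables entering the correlation matrix.
#' @param transforms Transform registry for the LMM responses.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `micdiv_run`: `plot_data` (merged plot table),
#'   `physiology`, `biomass_necromass`, `lmm_tests`, `correlations`,
#'   `sem`, `manifest`.
#' @export
run_pipeline <- function(plots, incubation, isotope, cfe, dna, aminosugars,
                         model = default_path_model(),
                         order = c("psr-first", "pfgr-first"),
                         mode = c("lenient", "strict"),
                         lmm_responses = NULL,
                         cor_variables = c("soc", "cmic", "growth", "q_growth",
                                           "cue", "resp", "q_resp", "root_c",
                                           "necromass_total"),
                         transforms = lmm_default_transforms(),
                         out_dir = NULL, seed = NULL) {
  order <- match.arg(order)
  mode <- match.arg(mode)
  plots <- read_input(plots, "plots")
  incubation <- read_input(incubation, "incubation")
  isotope <- read_input(isotope, "isotope")
  cfe <- read_input(cfe, "cfe")
  dna <- read_input(dna, "dna")
  aminosugars <- read_input(aminosugars, "aminosugars")
  check_columns(plots, c("plot_id", "block", "psr_sown", "pfgr",
                         "has_grasses", "has_legumes", "has_small_herbs",
                         "has_tall_herbs"), "plots")

  physiology <- compute_physiology(incubation, isotope, cfe, dna, mode = mode)
  if (!"plot_id" %in% names(physiology)) physiology$plot_id <- physiology$sample_id
  stoich <- compute_biomass_necromass(cfe, aminosugars, dna, mode = mode)

  plot_phys <- aggregate_physiology(physiology)
  nec_cols <- c("necromass_bacterial", "necromass_fungal", "necromass_total",
                "fb_ratio")
  stoich$plot_id <- physiology$plot_id[match(stoich$sample_id,
                                             physiology$sample_id)]
  plot_nec <- stats::aggregate(stoich[nec_cols],
                               by = list(plot_id = stoich$plot_id), FUN = mean)

  merged <- merge(merge(plots, plot_phys, by = "plot_id"),
                  plot_nec, by = "plot_id")
  merged$resp <- merged$respiration

  if (is.null(lmm_responses)) {
    lmm_responses <- intersect(
      c("soc", "doc", "root_c", "root_cn", "cmic", "growth", "q_growth",
        "turnover_time", "resp", "q_resp", "uptake", "q_uptake", "cue",
        "necromass_fungal", "necromass_bacterial", "necromass_total",
        "fb_ratio"),
      names(merged)
    )
  }
  lmm_tests <- do.call(rbind, lapply(lmm_responses, function(rv) {
    sequential_lr_tests(merged, rv, order = order, transforms = transforms)
  }))

  cor_vars <- intersect(cor_variables, names(merged))
  corrected <- block_correct_columns(merged, cor_vars)
  correlations <- correlation_matrix(corrected, cor_vars)

  sem <- sem_fit(model, merged)

  manifest <- list(
    package = "micdiv",
    version = as.character(utils::packageVersion("micdiv")),
    r_version = R.version.string,
    seed = seed, order = order, mode = mode,
    n_plots = nrow(merged), n_samples = nrow(physiology),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  result <- structure(list(
    plot_data = merged, physiology = physiology,
    biomass_necromass = stoich, lmm_tests = lmm_tests,
    correlations = correlations, sem = sem, manifest = manifest
  ), class = "micdiv_run")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(result$physiology, file.path(out_dir, "physiology.csv"),
                   row.names = FALSE)
  utils::write.csv(result$biomass_necromass,
                   file.path(out_dir, "biomass_necromass.csv"),
                   row.names = FALSE)
  utils::write.csv(result$lmm_tests, file.path(out_dir, "lmm_tests.csv"),
                   row.names = FALSE)
  cm <- result$correlations
  pairs <- which(lower.tri(cm$r), arr.ind = TRUE)
  utils::write.csv(data.frame(
    var1 = rownames(cm$r)[pairs[, 1]], var2 = colnames(cm$r)[pairs[, 2]],
    r = cm$r[pairs], p = cm$p[pairs], code = cm$code[pairs]
  ), file.path(out_dir, "correlations.csv"), row.names = FALSE)
  sem <- result$sem
  jsonlite::write_json(list(
    paths = sem$path_coefficients, dsep = sem$dsep,
    fisher_c = sem$fisher_c, aic = sem$aic, aicc = sem$aicc, K = sem$K,
    n = sem$n, r2 = as.data.frame(sem$r2)
  ), file.path(out_dir, "sem_fit.json"), auto_unbox = TRUE, digits = NA,
     dataframe = "columns")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.micdiv_run <- function(x, ...) {
  cat("micdiv pipeline run:", x$manifest$n_plots, "plots,",
      x$manifest$n_samples, "samples\n")
  cat("LMM tests:", length(unique(x$lmm_tests$response)), "responses;",
      "SEM Fisher's C =", format(x$sem$fisher_c$C, digits = 4),
      "on", x$sem$fisher_c$df, "df\n")
  invisible(x)
}

#' Summary statistics by sown species richness level
#'
#' One row per richness level with the sample size and the mean and SD of
#' each requested variable, in the same shape as
#' [psr_reference_summary()]. Levels without plots are omitted with a
#' warning.
#'
#' @param plots Plot-level data frame with a `psr_sown` column.
#' @param variables Variables to summarise; defaults to all numeric
#'   columns.
#' @return Data frame with columns `psr`, `n`, `<variable>_mean`,
#'   `<variable>_sd`.
#' @export
summarize_by_psr <- function(plots, variables = NULL) {
  check_columns(plots, "psr_sown", "plots")
  if (is.null(variables)) {
    variables <- setdiff(names(plots)[vapply(plots, is.numeric, TRUE)],
                         c("psr_sown", "pfgr", "block"))
  }
  levels_present <- sort(unique(plots$psr_sown))
  out <- data.frame(psr = levels_present,
                    n = as.integer(table(plots$psr_sown)[as.character(levels_present)]))
  for (v in variables) {
    out[[paste0(v, "_mean")]] <- as.numeric(
      tapply(plots[[v]], plots$psr_sown, mean)[as.character(levels_present)])
    out[[paste0(v, "_sd")]] <- as.numeric(
      tapply(plots[[v]], plots$psr_sown, stats::sd)[as.character(levels_present)])
  }
  rownames(out) <- NULL
  out
}

#' Change in a variable across the species richness gradient
#'
#' Contrasts the mean at the lowest richness level (monocultures) with the
#' mean at the highest level: percent increase and fold change.
#'
#' @param summary A summary table as returned by [summarize_by_psr()] or
#'   [psr_reference_summary()].
#' @param variable Variable name (without the `_mean` suffix).
#' @return Named numeric vector: `low`, `high`, `pct_increase`,
#'   `fold_change`.
#' @export
psr_change <- function(summary, variable) {
  col <- paste0(variable, "_mean")
  check_columns(summary, c("psr", col), "summary")
  lo <- summary[[col]][which.min(summary$psr)]
  hi <- summary[[col]][which.max(summary$psr)]
  if (lo <= 0) md_stop("baseline mean must be positive", "invalid_measurement")
  c(low = lo, high = hi, pct_increase = (hi / lo - 1) * 100,
    fold_change = hi / lo)
}
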