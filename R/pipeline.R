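# Deterministic per-stage child seeds derived from one global seed, so each
# stage can be re-run independently with identical results.
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, impute = 2L, reference = 3L, select = 4L, fit = 5L)
  ((as.integer(seed) %% 100000L) * 10007L + stages[[stage]] * 101L) %% 2000000000L
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> impute -> derive -> bivariate -> select -> fit ->
#' pool -> compare -> report as one seeded run, writing every artifact as CSV
#' into `outdir`: the cohort and its ground truth, the completed datasets and
#' imputation provenance, a gender summary table, nail-urine correlations,
#' percentile ranges, the stepwise selection tally, one pooled parameter
#' table per dependent variable, dose-response prediction curves for the
#' absolute outcomes, the cohort-vs-reference comparison, and a run log.
#'
#' @param config A [cohort_config()].
#' @param seed Global integer seed; per-stage child seeds are derived from it.
#' @param outdir Output directory (created).
#' @param m Number of imputations.
#' @param dependents Dependent variables to model.
#' @param selection Logical: run the stepwise-selection stage (the most
#'   expensive stage; skip for smoke runs).
#' @param comparison Logical: run the reference-survey comparison stage.
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `mi`, `tally`, `models`, `comparison`) and `outdir`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, outdir = "asmet_run",
                         m = 20, dependents = dependent_variables(),
                         selection = TRUE, comparison = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("asmet %s | R %s.%s", as.character(utils::packageVersion("asmet")),
            R.version$major, R.version$minor),
    sprintf("seed %d | n %d | m %d", seed, config$n_participants, m))

  cohort <- generate_cohort(config, seed = stage_seed(seed, "simulate"))
  write_cohort_csv(cohort, file.path(outdir, "cohort.csv"))
  write_truth_csv(config$truth, file.path(outdir, "truth.csv"))

  mi <- impute_nondetects(cohort, m = m, seed = stage_seed(seed, "impute"))
  write_mi_csv(mi, file.path(outdir, "imputed"))

  utils::write.csv(gender_table(mi), file.path(outdir, "table_gender.csv"),
                   row.names = FALSE)
  cors <- do.call(rbind, lapply(c("log10_tias", "log10_mma", "log10_dma"),
                                function(v) {
    pc <- pooled_correlation(mi, "log10_nail_tas", v)
    data.frame(x = "log10_nail_tas", y = v, r = pc$r, p.value = pc$p.value)
  }))
  utils::write.csv(cors, file.path(outdir, "correlations.csv"), row.names = FALSE)
  pct_vars <- c("pct_tias", "pct_mma", "pct_dma", "pmi", "smi")
  pcts <- do.call(rbind, lapply(pct_vars, function(v) {
    q <- percentile_range(mi, v)
    data.frame(variable = v, p01 = q[[1]], p99 = q[[2]])
  }))
  utils::write.csv(pcts, file.path(outdir, "percentiles.csv"), row.names = FALSE)

  tally <- NULL
  if (selection) {
    tally <- run_stepwise(mi, dependents = dependents)
    # retention threshold scales with the number of runs (25 of 180 at full scale)
    thr <- attr(tally, "total_runs") * 25 / 180
    td <- as.data.frame(tally)
    td$retained <- td$candidate %in% retain_predictors(tally, thr)
    utils::write.csv(td, file.path(outdir, "selection_tally.csv"),
                     row.names = FALSE)
    final_terms <- revise_selection(retain_predictors(tally, thr))
    writeLines(final_terms, file.path(outdir, "final_terms.txt"))
    log_lines <- c(log_lines,
                   sprintf("stepwise runs %d (failed %d)",
                           attr(tally, "total_runs"), attr(tally, "runs_failed")))
  }

  models <- list()
  for (dep in dependents) {
    pm <- fit_pooled_model(mi, dependent = dep)
    models[[dep]] <- pm
    utils::write.csv(pm$pooled, file.path(outdir, paste0("model_", dep, ".csv")),
                     row.names = FALSE)
  }
  for (dep in intersect(dependents, c("log10_tias", "log10_mma", "log10_dma"))) {
    params <- coef_to_parameters(stats::setNames(models[[dep]]$pooled$estimate,
                                                 models[[dep]]$pooled$parameter))
    curve <- predict_curve(params, mi$datasets[[1]])
    utils::write.csv(curve, file.path(outdir, paste0("predictions_", dep, ".csv")),
                     row.names = FALSE)
  }

  comp <- NULL
  if (comparison) {
    ref <- generate_reference_survey(config, seed = stage_seed(seed, "reference"))
    comp <- compare_cohort_to_reference(mi, cohort, ref)
    utils::write.csv(comp, file.path(outdir, "comparison.csv"), row.names = FALSE)
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(cohort = cohort, mi = mi, tally = tally, models = models,
                 comparison = comp, outdir = outdir))
}
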