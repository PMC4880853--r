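#' Weighted geometric mean under left censoring
#'
#' Weighted maximum-likelihood estimate of the mean log10 concentration from
#' a left-censored log-normal model (the survival-analysis formulation used
#' for survey data with non-detects), back-transformed to a geometric mean.
#' With no censoring and equal weights this is the ordinary geometric mean;
#' it is invariant to rescaling all weights.
#'
#' @param values Concentrations; non-detects carry their LOD.
#' @param nd Logical non-detect flags.
#' @param weights Positive survey weights (default equal).
#' @return List with `gm`, `mean_log10`, `sigma`.
#' @export
censored_weighted_gm <- function(values, nd, weights = NULL) {
  fit <- fit_censored_lognormal(values, nd, weights = weights)
  mu <- unname(fit$coefficients[1])
  list(gm = 10^mu, mean_log10 = mu, sigma = fit$sigma)
}

#' Age bands used for demographic post-stratification
#'
#' @param age Age in years.
#' @return Factor with levels `40-49`, `50-59`, `60-69`, `70-79`, `80+`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(40, 50, 60, 70, 80, Inf), right = FALSE,
      labels = c("40-49", "50-59", "60-69", "70-79", "80+"))
}

demographic_cells <- function(data) {
  interaction(data$gender, ifelse(data$race == "white", "white", "other"),
              age_band(data$age), drop = FALSE, sep = "|")
}

#' Post-stratify reference-survey weights to a target population
#'
#' Rescales reference weights within gender x race (white/other) x age-band
#' cells so that each cell's share of total weight equals the target
#' population's share of participants in that cell. Total weight is
#' preserved. Errors if a target cell with positive share is empty in the
#' reference.
#'
#' @param reference Data frame with `gender`, `race`, `age` and `weight`.
#' @param target Data frame with `gender`, `race`, `age` (e.g. a cohort);
#'   its empirical cell shares are the post-stratification targets.
#' @return Numeric vector of revised weights, aligned with `reference` rows.
#' @export
reweight_reference <- function(reference, target) {
  if (is.null(reference$weight) || any(reference$weight <= 0))
    stop("reference must carry strictly positive 'weight'")
  rc <- demographic_cells(reference)
  tc <- demographic_cells(target)
  target_share <- prop.table(table(tc))
  ref_wsum <- tapply(reference$weight, rc, sum)
  ref_wsum[is.na(ref_wsum)] <- 0
  need <- names(target_share)[target_share > 0]
  empty <- need[ref_wsum[need] == 0]
  if (length(empty))
    stop("reference has no observations in target cells: ",
         paste(empty, collapse = ", "))
  total <- sum(reference$weight)
  factors <- stats::setNames(rep(0, length(ref_wsum)), names(ref_wsum))
  factors[need] <- as.numeric(target_share[need]) * total / ref_wsum[need]
  unname(reference$weight * factors[as.character(rc)])
}

#' Compare cohort urinary arsenic levels with a reference survey
#'
#' For each urinary species computes the cohort geometric mean over the
#' completed datasets, the reference-survey geometric mean from a weighted
#' left-censored log-normal fit with weights post-stratified to the cohort's
#' gender x race x age-band distribution, their ratio, and the non-detect
#' percentage and mean detection limit on both sides.
#'
#' @param mi The cohort's `mi_cohort` (for completed geometric means).
#' @param cohort The observed cohort with `<species>_nd` flags (for
#'   non-detect rates; flagged cells carry their LOD).
#' @param reference Reference survey data frame with species columns,
#'   `<species>_nd` flags, `gender`, `race`, `age`, `weight`.
#' @param species Species column names shared by both tables.
#' @return Data frame, one row per species.
#' @export
compare_cohort_to_reference <- function(mi, cohort, reference,
                                        species = c("ias3", "ias5", "mma", "dma")) {
  missing_coh <- setdiff(species, names(cohort))
  missing_ref <- setdiff(species, names(reference))
  if (length(missing_coh) || length(missing_ref))
    stop("species absent: ",
         paste(unique(c(missing_coh, missing_ref)), collapse = ", "))
  w_rev <- reweight_reference(reference, cohort)
  rows <- lapply(species, function(sp) {
    nd_c <- cohort[[paste0(sp, "_nd")]]
    nd_r <- reference[[paste0(sp, "_nd")]]
    coh_gm <- 10^mean(vapply(mi$datasets, function(d) mean(log10(d[[sp]])),
                             numeric(1)))
    ref <- censored_weighted_gm(reference[[sp]], nd_r, weights = w_rev)
    data.frame(
      species = sp,
      cohort_gm = coh_gm,
      reference_gm = ref$gm,
      gm_ratio = coh_gm / ref$gm,
      cohort_nd_pct = 100 * mean(nd_c, na.rm = TRUE),
      reference_nd_pct = 100 * sum(w_rev * nd_r) / sum(w_rev),
      cohort_mean_lod = if (any(nd_c, na.rm = TRUE))
        mean(cohort[[sp]][which(nd_c)]) else NA_real_,
      reference_mean_lod = if (any(nd_r))
        sum((w_rev * reference[[sp]])[nd_r]) / sum(w_rev[nd_r]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic reference survey
#'
#' Reuses the cohort generator with the species geometric means shifted down
#' by `log10_shift` on the log10 scale (emulating a general-population survey
#' with much lower exposure, hence more non-detects) and attaches log-normal
#' survey weights.
#'
#' @param config A [cohort_config()]; its `target_gm` is divided by
#'   `10^log10_shift`.
#' @param log10_shift Downward shift of the species geometric means (log10
#'   units).
#' @param seed Integer seed.
#' @param weight_sdlog10 SD of the log10-normal survey weights.
#' @return A cohort data frame with an added `weight` column.
#' @export
generate_reference_survey <- function(config = cohort_config(), log10_shift = 0.8,
                                      seed = 2L, weight_sdlog10 = 0.2) {
  cfg <- config
  cfg$target_gm <- config$target_gm / 10^log10_shift
  cfg$truth <- center_truth(cfg$truth, cfg, cfg$target_gm)
  ref <- generate_cohort(cfg, seed = seed)
  ref$weight <- 10^stats::rnorm(nrow(ref), 0, weight_sdlog10)
  ref
}
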