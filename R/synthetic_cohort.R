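#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set for a seeded synthetic cohort with the
#' statistical structure the downstream analysis assumes: an older-adult
#' population (age >= 45) chronically using home tap water with arsenic from
#' below the detection limit up to a configurable maximum, urinary arsenic
#' species generated from a known-truth offset dose-response model and then
#' left-censored at their detection limits, plus realistic missingness.
#'
#' Covariate defaults emulate the structural features of the study population
#' the analysis was designed for: n = 904, 59% female, water LOD 3 ug/L with
#' water arsenic truncated at 1850 ug/L, urinary LODs 0.5/1/0.5/1 ug/L for
#' iAs(III)/iAs(V)/MMA/DMA, 93/904 zero tap-water consumers, 59/904 missing
#' toenail records, and one missing BMI/cotinine/creatinine record each.
#'
#' The ground-truth coefficient sets (`truth`) default to the reference
#' multivariate estimates for log10 TiAs, MMA and DMA, with the four
#' per-source intercepts shifted by one per-species constant so that the
#' implied geometric means under the configured covariate distributions equal
#' `target_gm`. The shift is computed deterministically by quadrature at
#' config-construction time (see [center_truth()]).
#'
#' @param n_participants Cohort size.
#' @param seed Default random seed used by [generate_cohort()].
#' @param water_lod Detection limit for water total arsenic, ug/L.
#' @param urine_lods Named numeric: detection limits (ug/L) for `ias3`,
#'   `ias5`, `mma`, `dma`.
#' @param nail_lod Detection limit for toenail total arsenic, ug/g.
#' @param water_source_probs Named probabilities over the four
#'   [water_sources()]; must sum to 1.
#' @param female_prob,white_prob,smoker_prob,fish_prob,alcohol_prob
#'   Bernoulli probabilities for the categorical covariates.
#' @param age_range Numeric length 2, minimum (>= 45) and maximum age.
#' @param age_prop_younger Proportion of participants below age 60.
#' @param bmi_meanlog10,bmi_sdlog10 Log10-normal BMI parameters (kg/m2).
#' @param water_meanlog10,water_sdlog10,water_max Truncated log10-normal for
#'   water arsenic (ug/L), upper-truncated at `water_max`.
#' @param zero_consumption_prob Probability of reporting zero tap-water
#'   consumption (recoded downstream to 0.06 L/day).
#' @param consumption_meanlog10,consumption_sdlog10 Log10-normal tap-water
#'   consumption (L/day) for non-zero consumers.
#' @param cotinine_smoker_meanlog10,cotinine_smoker_sdlog10 Log10-normal
#'   urinary cotinine (ug/L) for smokers.
#' @param cotinine_nonsmoker_meanlog10,cotinine_nonsmoker_sdlog10 Ditto for
#'   non-smokers.
#' @param creatinine_meanlog10,creatinine_sdlog10 Log10-normal urinary
#'   creatinine (mg/dL).
#' @param ias3_frac_mean,ias3_frac_conc Mean and concentration (a+b) of the
#'   Beta distribution for the iAs(III) share of TiAs; the default mean gives
#'   iAs(V) the smaller share and hence the higher non-detect rate.
#' @param nail_intercept,nail_slope,nail_sd Toenail model: `log10(NTAs) =
#'   nail_intercept + nail_slope * log10(10 + water_tas) + N(0, nail_sd)`.
#' @param missing_nail_rate,missing_bmi_rate,missing_cotinine_rate,missing_creatinine_rate
#'   Per-field missingness probabilities.
#' @param truth Named list of [model_parameters()] for `tias`, `mma`, `dma`
#'   (before centering), or `NULL` for the reference sets.
#' @param residual_sd Named numeric: residual SD on the log10 scale per
#'   species (`tias`, `mma`, `dma`).
#' @param residual_cor Common pairwise correlation of the three species'
#'   log-scale residuals.
#' @param target_gm Named numeric: geometric means (ug/L) the centered truth
#'   should imply for `tias`, `mma`, `dma`; `NULL` disables centering.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 904L,
                          seed = 1L,
                          water_lod = 3,
                          urine_lods = c(ias3 = 0.5, ias5 = 1, mma = 0.5, dma = 1),
                          nail_lod = 0.1,
                          water_source_probs = c(untreated = 0.40, filtered = 0.15,
                                                 other_treatment = 0.25, bottled = 0.20),
                          female_prob = 0.59,
                          age_range = c(45, 92),
                          age_prop_younger = 0.45,
                          bmi_meanlog10 = log10(28.4), bmi_sdlog10 = 0.06,
                          white_prob = 0.90,
                          water_meanlog10 = 1.6, water_sdlog10 = 0.55,
                          water_max = 1850,
                          zero_consumption_prob = 93 / 904,
                          consumption_meanlog10 = 0, consumption_sdlog10 = 0.25,
                          smoker_prob = 0.16,
                          cotinine_smoker_meanlog10 = 3, cotinine_smoker_sdlog10 = 0.4,
                          cotinine_nonsmoker_meanlog10 = 0.5,
                          cotinine_nonsmoker_sdlog10 = 0.5,
                          creatinine_meanlog10 = 2, creatinine_sdlog10 = 0.25,
                          fish_prob = 0.29,
                          alcohol_prob = 0.38,
                          ias3_frac_mean = 0.65, ias3_frac_conc = 10,
                          nail_intercept = -1.2, nail_slope = 0.5, nail_sd = 0.3,
                          missing_nail_rate = 59 / 904,
                          missing_bmi_rate = 1 / 904,
                          missing_cotinine_rate = 1 / 904,
                          missing_creatinine_rate = 1 / 904,
                          truth = NULL,
                          residual_sd = c(tias = 0.45, mma = 0.40, dma = 0.30),
                          residual_cor = 0.5,
                          target_gm = c(tias = 1.87, mma = 1.95, dma = 3.81)) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  if (is.null(cfg$truth)) cfg$truth <- reference_truth()
  validate_cohort_config(cfg)
  if (!is.null(target_gm)) cfg$truth <- center_truth(cfg$truth, cfg, target_gm)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid cohort config field '", field, "': ",
                                    msg, call. = FALSE)
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    fail("n_participants", "must be a positive count")
  if (cfg$water_lod <= 0) fail("water_lod", "must be > 0")
  if (!setequal(names(cfg$urine_lods), c("ias3", "ias5", "mma", "dma")))
    fail("urine_lods", "must name ias3, ias5, mma, dma")
  if (any(cfg$urine_lods <= 0)) fail("urine_lods", "all LODs must be > 0")
  if (cfg$nail_lod <= 0) fail("nail_lod", "must be > 0")
  if (!setequal(names(cfg$water_source_probs), water_sources()))
    fail("water_source_probs", "must name the four water sources")
  if (abs(sum(cfg$water_source_probs) - 1) > 1e-8)
    fail("water_source_probs", "must sum to 1")
  if (any(cfg$water_source_probs < 0)) fail("water_source_probs", "must be >= 0")
  if (cfg$age_range[1] < 45) fail("age_range", "minimum age must be >= 45")
  if (cfg$age_range[2] <= cfg$age_range[1]) fail("age_range", "max must exceed min")
  for (p in c("female_prob", "white_prob", "smoker_prob", "fish_prob",
              "alcohol_prob", "zero_consumption_prob", "age_prop_younger",
              "missing_nail_rate", "missing_bmi_rate", "missing_cotinine_rate",
              "missing_creatinine_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) fail(p, "must be a probability in [0, 1]")
  }
  if (cfg$water_max <= cfg$water_lod) fail("water_max", "must exceed water_lod")
  if (cfg$ias3_frac_mean <= 0 || cfg$ias3_frac_mean >= 1)
    fail("ias3_frac_mean", "must lie strictly in (0, 1)")
  if (cfg$ias3_frac_conc <= 0) fail("ias3_frac_conc", "must be > 0")
  if (!is.null(cfg$truth)) {
    if (!setequal(names(cfg$truth), c("tias", "mma", "dma")))
      fail("truth", "must name tias, mma, dma")
    ok <- vapply(cfg$truth, inherits, logical(1), "model_parameters")
    if (!all(ok)) fail("truth", "entries must be model_parameters objects")
  }
  if (!setequal(names(cfg$residual_sd), c("tias", "mma", "dma")) ||
      any(cfg$residual_sd < 0))
    fail("residual_sd", "must name tias, mma, dma and be >= 0")
  if (cfg$residual_cor < -1 || cfg$residual_cor > 1)
    fail("residual_cor", "must be a correlation in [-1, 1]")
  invisible(cfg)
}

# Expected value of g(W) under the config's upper-truncated log10-normal
# water-arsenic distribution, by adaptive quadrature on the z scale.
water_expectation <- function(cfg, g) {
  zmax <- (log10(cfg$water_max) - cfg$water_meanlog10) / cfg$water_sdlog10
  mass <- stats::pnorm(zmax)
  f <- function(z) g(10^(cfg$water_meanlog10 + cfg$water_sdlog10 * z)) * stats::dnorm(z)
  stats::integrate(f, -8, zmax, rel.tol = 1e-10)$value / mass
}

# Expected log10 age under the two-piece uniform age model.
expected_log10_age <- function(cfg) {
  a <- cfg$age_range[1]; b <- 60; cc <- cfg$age_range[2]
  p <- cfg$age_prop_younger
  mean_log10_unif <- function(lo, hi) {
    (hi * (log(hi) - 1) - lo * (log(lo) - 1)) / ((hi - lo) * log(10))
  }
  if (cfg$age_range[2] <= 60) return(mean_log10_unif(a, cc))
  p * mean_log10_unif(a, b) + (1 - p) * mean_log10_unif(b, cc)
}

#' Center ground-truth intercepts to target geometric means
#'
#' Shifts the four per-source intercepts of each species' ground-truth
#' coefficient set by a single constant so that the expected log10
#' concentration under the configured covariate distributions equals
#' `log10(target_gm)`. All slope and covariate coefficients are left
#' untouched; only the overall level moves. Deterministic (quadrature for the
#' water term, closed forms elsewhere).
#'
#' @param truth Named list of [model_parameters()] for `tias`, `mma`, `dma`.
#' @param cfg A `cohort_config` (centering uses its covariate distributions).
#' @param target_gm Named numeric of target geometric means, ug/L.
#' @return The truth list with shifted intercepts.
#' @export
center_truth <- function(truth, cfg, target_gm) {
  e_log10_cons <- cfg$zero_consumption_prob * log10(0.06) +
    (1 - cfg$zero_consumption_prob) * cfg$consumption_meanlog10
  e_log10_cot <- cfg$smoker_prob * cfg$cotinine_smoker_meanlog10 +
    (1 - cfg$smoker_prob) * cfg$cotinine_nonsmoker_meanlog10
  e_log10_age <- expected_log10_age(cfg)
  for (sp in names(truth)) {
    par <- truth[[sp]]
    e_water_term <- water_expectation(
      cfg, function(w) transform_water_as(w, par$alpha_log_offset))
    e_lp <- sum(cfg$water_source_probs[names(par$alpha)] * par$alpha) +
      sum(cfg$water_source_probs[names(par$beta)] * par$beta) * e_water_term +
      par$beta_q * e_log10_cons +
      par$beta_c * cfg$creatinine_meanlog10 +
      par$beta_f * cfg$female_prob +
      par$beta_b * cfg$bmi_meanlog10 +
      par$beta_a * e_log10_age +
      par$beta_s * e_log10_cot +
      par$beta_r * cfg$fish_prob
    shift <- log10(target_gm[[sp]]) - e_lp
    par$alpha <- par$alpha + shift
    truth[[sp]] <- par
  }
  truth
}

#' Left-censor a vector of concentrations at a detection limit
#'
#' Values strictly below `lod` are flagged as non-detects and carry the LOD
#' itself (not a concentration); values at or above the LOD are returned
#' unchanged with a clear flag.
#'
#' @param values Non-negative concentrations.
#' @param lod Detection limit, `> 0`.
#' @return A list with components `value` and `nd` (logical non-detect flag).
#' @examples
#' apply_censoring(c(0.4, 0.6), lod = 0.5)
#' @export
apply_censoring <- function(values, lod) {
  if (lod <= 0) stop("detection limit must be > 0")
  if (any(values < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  nd <- !is.na(values) & values < lod
  out <- values
  out[nd] <- lod
  list(value = out, nd = nd)
}

#' Generate a seeded synthetic cohort
#'
#' Draws covariates from the configured distributions, computes expected
#' log10 TiAs/MMA/DMA from the ground-truth offset dose-response model, adds
#' correlated Gaussian residuals on the log10 scale, splits TiAs into
#' iAs(III) and iAs(V) by a Beta-distributed fraction, then applies left
#' censoring at each analyte's detection limit and the configured
#' missingness. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame of class `as_cohort`, one row per participant, with
#'   paired `<analyte>` / `<analyte>_nd` columns for censored measurements and
#'   `NA` for missing cells. The config is attached as attribute `"config"`
#'   and the pre-censoring species values as attribute `"latent"` (used by
#'   recovery tests; not part of the observed data).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  n <- as.integer(config$n_participants)

  gender <- ifelse(stats::runif(n) < config$female_prob, "female", "male")
  younger <- stats::runif(n) < config$age_prop_younger
  age <- ifelse(younger,
                stats::runif(n, config$age_range[1], min(60, config$age_range[2])),
                stats::runif(n, min(60, config$age_range[2]), config$age_range[2]))
  bmi <- 10^stats::rnorm(n, config$bmi_meanlog10, config$bmi_sdlog10)
  race <- ifelse(stats::runif(n) < config$white_prob, "white", "other")
  water_source <- sample(water_sources(), n, replace = TRUE,
                         prob = config$water_source_probs[water_sources()])
  # upper-truncated log10-normal water arsenic via inverse CDF
  zmax <- (log10(config$water_max) - config$water_meanlog10) / config$water_sdlog10
  wz <- stats::qnorm(stats::runif(n) * stats::pnorm(zmax))
  water_tas_true <- 10^(config$water_meanlog10 + config$water_sdlog10 * wz)
  zero_cons <- stats::runif(n) < config$zero_consumption_prob
  tap_water_consumption <- ifelse(
    zero_cons, 0,
    10^stats::rnorm(n, config$consumption_meanlog10, config$consumption_sdlog10))
  smoker <- stats::runif(n) < config$smoker_prob
  cotinine <- ifelse(
    smoker,
    10^stats::rnorm(n, config$cotinine_smoker_meanlog10, config$cotinine_smoker_sdlog10),
    10^stats::rnorm(n, config$cotinine_nonsmoker_meanlog10, config$cotinine_nonsmoker_sdlog10))
  creatinine <- 10^stats::rnorm(n, config$creatinine_meanlog10, config$creatinine_sdlog10)
  recent_fish <- as.integer(stats::runif(n) < config$fish_prob)
  recent_alcohol <- as.integer(stats::runif(n) < config$alcohol_prob)

  covars <- data.frame(
    water_source = water_source, water_tas = water_tas_true,
    tap_water_consumption = tap_water_consumption, creatinine = creatinine,
    gender = gender, bmi = bmi, age = age, cotinine = cotinine,
    recent_fish = recent_fish)

  sp_names <- c("tias", "mma", "dma")
  mu <- vapply(sp_names, function(sp) predict_response(config$truth[[sp]], covars),
               numeric(n))
  sds <- config$residual_sd[sp_names]
  cormat <- matrix(config$residual_cor, 3, 3); diag(cormat) <- 1
  sigma <- diag(sds) %*% cormat %*% diag(sds)
  resid <- if (all(sds == 0)) matrix(0, n, 3) else MASS::mvrnorm(n, c(0, 0, 0), sigma)
  log10_species <- mu + resid
  tias_true <- 10^log10_species[, 1]
  mma_true <- 10^log10_species[, 2]
  dma_true <- 10^log10_species[, 3]
  frac <- stats::rbeta(n, config$ias3_frac_mean * config$ias3_frac_conc,
                       (1 - config$ias3_frac_mean) * config$ias3_frac_conc)
  ias3_true <- frac * tias_true
  ias5_true <- (1 - frac) * tias_true

  nail_true <- 10^(config$nail_intercept +
                     config$nail_slope * log10(10 + water_tas_true) +
                     stats::rnorm(n, 0, config$nail_sd))

  water_cens <- apply_censoring(water_tas_true, config$water_lod)
  ias3_cens <- apply_censoring(ias3_true, config$urine_lods[["ias3"]])
  ias5_cens <- apply_censoring(ias5_true, config$urine_lods[["ias5"]])
  mma_cens <- apply_censoring(mma_true, config$urine_lods[["mma"]])
  dma_cens <- apply_censoring(dma_true, config$urine_lods[["dma"]])
  nail_cens <- apply_censoring(nail_true, config$nail_lod)

  cohort <- data.frame(
    id = seq_len(n),
    gender = gender, age = age, bmi = bmi, race = race,
    water_source = water_source,
    water_tas = water_cens$value, water_tas_nd = water_cens$nd,
    tap_water_consumption = tap_water_consumption,
    cotinine = cotinine, creatinine = creatinine,
    recent_fish = recent_fish, recent_alcohol = recent_alcohol,
    nail_tas = nail_cens$value, nail_tas_nd = nail_cens$nd,
    ias3 = ias3_cens$value, ias3_nd = ias3_cens$nd,
    ias5 = ias5_cens$value, ias5_nd = ias5_cens$nd,
    mma = mma_cens$value, mma_nd = mma_cens$nd,
    dma = dma_cens$value, dma_nd = dma_cens$nd,
    stringsAsFactors = FALSE)

  miss_nail <- stats::runif(n) < config$missing_nail_rate
  cohort$nail_tas[miss_nail] <- NA_real_
  cohort$nail_tas_nd[miss_nail] <- NA
  cohort$bmi[stats::runif(n) < config$missing_bmi_rate] <- NA_real_
  cohort$cotinine[stats::runif(n) < config$missing_cotinine_rate] <- NA_real_
  cohort$creatinine[stats::runif(n) < config$missing_creatinine_rate] <- NA_real_

  attr(cohort, "config") <- config
  attr(cohort, "latent") <- data.frame(
    tias = tias_true, mma = mma_true, dma = dma_true,
    ias3 = ias3_true, ias5 = ias5_true, nail_tas = nail_true,
    water_tas = water_tas_true)
  class(cohort) <- c("as_cohort", "data.frame")
  cohort
}

#' Write / read a cohort table as CSV
#'
#' One row per participant; censoring is encoded as paired `<analyte>` and
#' `<analyte>_nd` columns (the `<analyte>` column holds the LOD for
#' non-detects), missingness as empty cells.
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in grep("_nd$", names(df), value = TRUE)) df[[col]] <- as.logical(df[[col]])
  class(df) <- c("as_cohort", "data.frame")
  df
}

#' Write generator ground truth to a sidecar CSV
#'
#' Flattens the per-species ground-truth coefficient sets into a long table
#' (`species`, `parameter`, `value`) so parameter-recovery checks can be run
#' against generated cohorts without access to the config object.
#'
#' @param truth Named list of [model_parameters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  rows <- do.call(rbind, lapply(names(truth), function(sp) {
    p <- truth[[sp]]
    data.frame(
      species = sp,
      parameter = c(paste0("alpha_", names(p$alpha)), paste0("beta_", names(p$beta)),
                    "alpha_log_offset", "beta_q", "beta_c", "beta_f", "beta_b",
                    "beta_a", "beta_s", "beta_r"),
      value = c(unname(p$alpha), unname(p$beta), p$alpha_log_offset, p$beta_q,
                p$beta_c, p$beta_f, p$beta_b, p$beta_a, p$beta_s, p$beta_r))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
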