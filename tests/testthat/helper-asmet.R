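# Shared fixtures, built in code.

# Ground truth with every covariate effect zero: species are pure
# log-normal noise around fixed geometric means (used for null simulations).
null_truth <- function(gm = c(tias = 2, mma = 2, dma = 4)) {
  src <- water_sources()
  mk <- function(g) model_parameters(
    alpha = stats::setNames(rep(log10(g), 4), src),
    beta = stats::setNames(rep(0, 4), src), alpha_log_offset = 1)
  list(tias = mk(gm[["tias"]]), mma = mk(gm[["mma"]]), dma = mk(gm[["dma"]]))
}

# Small cohorts for fast pipeline exercises.
smoke_config <- function(n = 200, ...) {
  cohort_config(n_participants = n, ...)
}

# A completed (uncensored, no-missingness) dataset built from the
# generator's latent values, for oracle fits.
completed_from_latent <- function(config, seed) {
  stopifnot(config$missing_nail_rate == 0, config$missing_bmi_rate == 0,
            config$missing_cotinine_rate == 0, config$missing_creatinine_rate == 0)
  coh <- generate_cohort(config, seed = seed)
  lat <- attr(coh, "latent")
  d <- as.data.frame(coh)
  for (v in c("ias3", "ias5", "mma", "dma", "water_tas", "nail_tas"))
    d[[v]] <- lat[[v]]
  add_derived_variables(d)
}

no_missing_config <- function(...) {
  cohort_config(missing_nail_rate = 0, missing_bmi_rate = 0,
                missing_cotinine_rate = 0, missing_creatinine_rate = 0, ...)
}

# Independent brute-force implementation of the combining rules, kept
# deliberately naive (explicit loops, textbook formulas).
oracle_rubin <- function(q, u) {
  m <- length(q)
  qbar <- 0
  for (i in 1:m) qbar <- qbar + q[i] / m
  w <- 0
  for (i in 1:m) w <- w + u[i] / m
  b <- 0
  for (i in 1:m) b <- b + (q[i] - qbar)^2 / (m - 1)
  tot <- w + (1 + 1 / m) * b
  nu <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  tstat <- qbar / sqrt(tot)
  p <- if (is.finite(nu)) 2 * stats::pt(-abs(tstat), nu) else 2 * stats::pnorm(-abs(tstat))
  list(estimate = qbar, within = w, between = b, total = tot, df = nu,
       statistic = tstat, p.value = p)
}

# Wrap completed data frames as an mi_cohort without running the imputer.
as_mi <- function(datasets) {
  structure(list(datasets = datasets,
                 provenance = data.frame(m = integer(0), row = integer(0),
                                         column = character(0), reason = character(0)),
                 m = length(datasets)),
            class = "mi_cohort")
}
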