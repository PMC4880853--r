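#' Derived urinary arsenic variables for a completed species panel
#'
#' From completed (strictly positive) urinary iAs(III), iAs(V), MMA and DMA
#' concentrations computes: total inorganic arsenic `TiAs = iAs3 + iAs5`, the
#' speciated sum `USAs = TiAs + MMA + DMA`, relative percentages with USAs as
#' denominator, the primary methylation index `PMI = MMA / TiAs` and
#' secondary methylation index `SMI = DMA / MMA`. By construction
#' `%TiAs + %MMA + %DMA = 100` and `PMI * SMI = DMA / TiAs`.
#'
#' @param panel Named list or vector with positive elements `ias3`, `ias5`,
#'   `mma`, `dma` (ug/L). Elements may be vectors of equal length.
#' @return A list with elements `tias`, `usas`, `pct_tias`, `pct_mma`,
#'   `pct_dma`, `pmi`, `smi`.
#' @examples
#' compute_derived(list(ias3 = 0.5, ias5 = 0.5, mma = 1, dma = 2))
#' @export
compute_derived <- function(panel) {
  panel <- as.list(panel)
  need <- c("ias3", "ias5", "mma", "dma")
  if (!all(need %in% names(panel)))
    stop("panel must contain ias3, ias5, mma, dma")
  if (any(unlist(panel[need]) <= 0, na.rm = TRUE))
    stop("all species concentrations must be strictly positive in completed data")
  tias <- panel$ias3 + panel$ias5
  usas <- tias + panel$mma + panel$dma
  list(
    tias = tias,
    usas = usas,
    pct_tias = 100 * tias / usas,
    pct_mma = 100 * panel$mma / usas,
    pct_dma = 100 * panel$dma / usas,
    pmi = panel$mma / tias,
    smi = panel$dma / panel$mma)
}

#' Add derived analysis columns to a completed cohort
#'
#' Appends the [compute_derived()] quantities plus the nine dependent
#' variables used for modeling: `log10_tias`, `log10_mma`, `log10_dma`,
#' `log10_usas`, `logit_pct_tias`, `logit_pct_mma`, `logit_pct_dma`,
#' `log10_pmi`, `log10_smi`.
#'
#' @param data Completed cohort data frame (no non-detect or missing cells in
#'   the urinary panel).
#' @return `data` with the derived columns appended.
#' @export
add_derived_variables <- function(data) {
  d <- compute_derived(data[c("ias3", "ias5", "mma", "dma")])
  data$tias <- d$tias
  data$usas <- d$usas
  data$pct_tias <- d$pct_tias
  data$pct_mma <- d$pct_mma
  data$pct_dma <- d$pct_dma
  data$pmi <- d$pmi
  data$smi <- d$smi
  data$log10_tias <- log10(d$tias)
  data$log10_mma <- log10(data$mma)
  data$log10_dma <- log10(data$dma)
  data$log10_usas <- log10(d$usas)
  data$logit_pct_tias <- logit_percent(d$pct_tias)
  data$logit_pct_mma <- logit_percent(d$pct_mma)
  data$logit_pct_dma <- logit_percent(d$pct_dma)
  data$log10_pmi <- log10(d$pmi)
  data$log10_smi <- log10(d$smi)
  if (!is.null(data$nail_tas)) data$log10_nail_tas <- log10(data$nail_tas)
  if (!is.null(data$water_tas)) data$log10_water_tas <- log10(data$water_tas)
  data
}

#' The nine modeled dependent variables
#'
#' @return Character vector of column names produced by
#'   [add_derived_variables()]: log10-transformed TiAs, MMA, DMA and USAs
#'   concentrations, logit-transformed relative percentages, and
#'   log10-transformed methylation indices.
#' @export
dependent_variables <- function() {
  c("log10_tias", "log10_mma", "log10_dma", "log10_usas",
    "logit_pct_tias", "logit_pct_mma", "logit_pct_dma",
    "log10_pmi", "log10_smi")
}

#' Logit transform of a percentage
#'
#' `ln((p/100) / (1 - p/100))` after clipping `p` into
#' `[clip_lo, 100 - clip_lo]` (default floor 0.1%) so that boundary values
#' from completed data stay finite. Round-trips with [inv_logit_percent()] on
#' the open interval.
#'
#' @param p Percentage value(s) in `[0, 100]`.
#' @param clip_lo Clipping floor, percent.
#' @return Logit value(s).
#' @export
logit_percent <- function(p, clip_lo = 0.1) {
  p <- pmin(pmax(p, clip_lo), 100 - clip_lo)
  q <- p / 100
  log(q / (1 - q))
}

#' @rdname logit_percent
#' @param x Logit value(s).
#' @export
inv_logit_percent <- function(x) {
  100 / (1 + exp(-x))
}

#' Recode zero tap-water consumption
#'
#' Reported daily tap-water consumption of exactly zero is recoded to 0.06
#' L/day (one-quarter cup) so the variable can be log-transformed; positive
#' values pass through unchanged.
#'
#' @param liters Daily consumption, L/day, `>= 0`.
#' @return Recoded consumption.
#' @export
recode_water_consumption <- function(liters) {
  if (any(liters < 0, na.rm = TRUE))
    stop("tap-water consumption must be non-negative")
  ifelse(liters == 0, 0.06, liters)
}

#' Smoking category from creatinine-corrected cotinine
#'
#' Classifies a participant as smoker when urinary cotinine corrected for
#' creatinine (ng cotinine per mg creatinine) exceeds a cutoff. With cotinine
#' in ug/L (= ng/mL) and creatinine in mg/dL the corrected value is
#' `100 * cotinine / creatinine`.
#'
#' @param cotinine Urinary cotinine, ug/L.
#' @param creatinine Urinary creatinine, mg/dL, `> 0`.
#' @param cutoff Cutoff in ng cotinine per mg creatinine (default 100).
#' @return Character vector, `"smoker"` or `"nonsmoker"`.
#' @export
smoking_category <- function(cotinine, creatinine, cutoff = 100) {
  if (any(creatinine <= 0, na.rm = TRUE))
    stop("creatinine must be strictly positive")
  corrected <- 100 * cotinine / creatinine
  ifelse(corrected > cutoff, "smoker", "nonsmoker")
}

#' Arsenic exposure from cigarette smoking relative to drinking water
#'
#' Aggregate-exposure arithmetic: daily arsenic intake from smoking is
#' `cigs_per_day * as_per_cig` and its share of total daily intake adds the
#' drinking-water contribution `water_liters * water_conc` to the
#' denominator. At 16 cigarettes/day and 0.0104 ug arsenic per cigarette the
#' smoking intake is 0.17 ug/day, about 0.8% of total intake for a person
#' drinking 2 L/day of water at 10 ug/L.
#'
#' @param cigs_per_day Cigarettes smoked per day.
#' @param as_per_cig Arsenic in smoke per cigarette, ug.
#' @param water_liters Daily drinking-water consumption, L.
#' @param water_conc Water arsenic concentration, ug/L.
#' @return List with `daily_smoking_as` (ug/day, reported to 2 decimals) and
#'   `fraction_of_total` (percent, reported to 1 decimal).
#' @examples
#' cigarette_exposure_fraction(16, 0.0104, 2, 10)
#' @export
cigarette_exposure_fraction <- function(cigs_per_day, as_per_cig,
                                        water_liters, water_conc) {
  if (any(c(cigs_per_day, as_per_cig, water_liters, water_conc) < 0))
    stop("all inputs must be non-negative")
  smoking_as <- cigs_per_day * as_per_cig
  total <- smoking_as + water_liters * water_conc
  if (total <= 0) stop("total daily arsenic intake must be positive")
  list(daily_smoking_as = round(smoking_as, 2),
       fraction_of_total = round(100 * smoking_as / total, 1))
}

#' Non-detect percentage from counts
#'
#' @param count Number of non-detect samples.
#' @param n Total number of samples.
#' @return Percentage of non-detects.
#' @export
nondetect_percent <- function(count, n) {
  if (n <= 0) stop("n must be positive")
  if (any(count < 0) || any(count > n)) stop("count must lie in [0, n]")
  stats::setNames(100 * as.vector(count) / n, names(count))
}

#' Urinary non-detect counts observed in the Churchill County cohort
#'
#' The published per-species counts of urine samples below the detection
#' limit among the 904 study participants, used as fixed inputs for
#' summaries: iAs(III) 289, iAs(V) 583, MMA 217, DMA 46.
#'
#' @return Named integer vector with attribute `n` = 904.
#' @export
churchill_nondetect_counts <- function() {
  structure(c(ias3 = 289L, ias5 = 583L, mma = 217L, dma = 46L), n = 904L)
}
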