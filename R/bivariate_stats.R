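#' Group geometric means with an imputation-pooled test
#'
#' For a strictly positive variable, computes the geometric mean per level of
#' a two-level grouping variable as `10^(mean log10)` averaged over the
#' completed datasets, and tests the between-group difference in mean log10
#' per imputation (two-sample linear model), combining the per-imputation
#' differences with [rubin_pool()].
#'
#' @param mi An `mi_cohort` from [impute_nondetects()].
#' @param variable Name of a strictly positive column in the completed data.
#' @param group Name of a grouping column with exactly two levels.
#' @return List with `gm` (named per-group geometric means), `difference`
#'   (pooled difference in mean log10, second level minus first), and
#'   `p.value` (pooled).
#' @export
group_geometric_means <- function(mi, variable, group) {
  lev <- sort(unique(mi$datasets[[1]][[group]]))
  if (length(lev) != 2) stop("'group' must have exactly two levels")
  ests <- vars <- numeric(mi$m)
  gm_log <- matrix(0, mi$m, 2)
  for (im in seq_len(mi$m)) {
    d <- mi$datasets[[im]]
    if (any(d[[variable]] <= 0)) stop("'variable' must be strictly positive")
    y <- log10(d[[variable]])
    g <- factor(d[[group]], levels = lev)
    if (min(table(g)) < 2) stop("each group needs at least two members")
    fit <- stats::lm(y ~ g)
    ests[im] <- stats::coef(fit)[2]
    vars[im] <- stats::vcov(fit)[2, 2]
    gm_log[im, ] <- tapply(y, g, mean)
  }
  pooled <- rubin_pool(ests, vars)
  list(gm = stats::setNames(10^colMeans(gm_log), lev),
       difference = pooled$estimate, se = pooled$se, p.value = pooled$p.value)
}

#' Imputation-pooled correlation via Fisher's z
#'
#' Computes the Pearson correlation of two (already transformed) columns in
#' each completed dataset, applies the Fisher z transform with variance
#' `1/(n-3)`, pools the z values with [rubin_pool()], and back-transforms the
#' pooled z to a correlation.
#'
#' @param mi An `mi_cohort`.
#' @param x,y Column names.
#' @return List with `r` (pooled correlation), `p.value`, and the pooled z
#'   result under `z`.
#' @export
pooled_correlation <- function(mi, x, y) {
  n <- nrow(mi$datasets[[1]])
  zs <- numeric(mi$m)
  for (im in seq_len(mi$m)) {
    d <- mi$datasets[[im]]
    if (stats::sd(d[[x]]) == 0 || stats::sd(d[[y]]) == 0)
      stop("correlation undefined: a variable has zero variance")
    r <- stats::cor(d[[x]], d[[y]])
    if (abs(r) >= 1 - 1e-14) {
      return(list(r = sign(r), p.value = 0, z = NULL))
    }
    zs[im] <- atanh(r)
  }
  pooled <- rubin_pool(zs, rep(1 / (n - 3), mi$m))
  list(r = tanh(pooled$estimate), p.value = pooled$p.value, z = pooled)
}

#' Percentile interval across all imputed datasets
#'
#' Percentiles are computed on the values pooled over all completed datasets
#' (each imputation contributes one copy of every observation), using linear
#' interpolation between order statistics.
#'
#' @param mi An `mi_cohort`.
#' @param variable Column name.
#' @param probs Probabilities (default 1st and 99th percentiles).
#' @return Named numeric vector of percentiles.
#' @export
percentile_range <- function(mi, variable, probs = c(0.01, 0.99)) {
  vals <- unlist(lapply(mi$datasets, function(d) d[[variable]]), use.names = FALSE)
  if (!length(vals)) stop("no observations for variable ", variable)
  stats::quantile(vals, probs = probs, type = 7, names = TRUE)
}

#' Imputation-pooled linear trend test
#'
#' Tests for a linear trend of an outcome column on a log10-transformed
#' predictor, per imputation, pooled by Rubin's rules. Used for age-trend
#' analyses of the transformed urinary outcomes.
#'
#' @param mi An `mi_cohort`.
#' @param outcome Outcome column name (already transformed).
#' @param predictor Positive predictor column; entered as `log10(predictor)`.
#' @return A `pooled_result` for the slope.
#' @export
pooled_trend <- function(mi, outcome, predictor) {
  ests <- vars <- numeric(mi$m)
  for (im in seq_len(mi$m)) {
    d <- mi$datasets[[im]]
    fit <- stats::lm(d[[outcome]] ~ log10(d[[predictor]]))
    ests[im] <- stats::coef(fit)[2]
    vars[im] <- stats::vcov(fit)[2, 2]
  }
  rubin_pool(ests, vars)
}

#' Gender-effect summary table
#'
#' A compact analogue of the published gender table: per-gender geometric
#' means for TiAs, MMA, DMA and the methylation indices, mean relative
#' percentages, with imputation-pooled p-values (log10-scale tests for
#' geometric means, logit-scale tests for percentages).
#'
#' @param mi An `mi_cohort` whose datasets carry derived columns.
#' @return Data frame with one row per quantity.
#' @export
gender_table <- function(mi) {
  conc <- c(tias = "tias", mma = "mma", dma = "dma", pmi = "pmi", smi = "smi")
  rows <- lapply(names(conc), function(v) {
    g <- group_geometric_means(mi, conc[[v]], "gender")
    data.frame(quantity = paste0("gm_", v),
               female = g$gm[["female"]], male = g$gm[["male"]],
               p.value = g$p.value)
  })
  pcts <- c(pct_tias = "logit_pct_tias", pct_mma = "logit_pct_mma",
            pct_dma = "logit_pct_dma")
  rows2 <- lapply(names(pcts), function(v) {
    ests <- vars <- numeric(mi$m)
    means <- matrix(0, mi$m, 2)
    for (im in seq_len(mi$m)) {
      d <- mi$datasets[[im]]
      g <- factor(d$gender, levels = c("female", "male"))
      fit <- stats::lm(d[[pcts[[v]]]] ~ g)
      ests[im] <- stats::coef(fit)[2]
      vars[im] <- stats::vcov(fit)[2, 2]
      means[im, ] <- tapply(d[[sub("logit_", "", pcts[[v]])]], g, mean)
    }
    pooled <- rubin_pool(ests, vars)
    data.frame(quantity = paste0("mean_", v),
               female = colMeans(means)[1], male = colMeans(means)[2],
               p.value = pooled$p.value)
  })
  out <- do.call(rbind, c(rows, rows2))
  rownames(out) <- NULL
  out
}
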