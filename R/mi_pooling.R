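#' Combine multiply-imputed estimates by Rubin's rules
#'
#' Given one estimate and its squared standard error per imputed dataset,
#' computes the pooled estimate (mean of estimates), within-imputation
#' variance `W` (mean of variances), between-imputation variance `B` (sample
#' variance of estimates), total variance `T = W + (1 + 1/M) B`, the
#' large-sample degrees of freedom
#' `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2`, and a two-sided p-value for the
#' null `theta = theta0` from the t reference with `nu` degrees of freedom.
#' When `B = 0` the degrees of freedom are infinite and the normal reference
#' is used.
#'
#' @param estimates Numeric vector of per-imputation estimates (length `M >= 2`).
#' @param variances Numeric vector of per-imputation squared standard errors.
#' @param theta0 Null value for the test (default 0).
#' @return Object of class `pooled_result`: list with `estimate`, `se`,
#'   `within`, `between`, `total`, `df`, `statistic`, `p.value`, `m`.
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))  # pooled 2, W 1, B 1, T 7/3, df 6.125
#' @export
rubin_pool <- function(estimates, variances, theta0 = 0) {
  if (length(estimates) != length(variances))
    stop("'estimates' and 'variances' must have the same length")
  m <- length(estimates)
  if (m < 2) stop("at least two imputations are required for pooling")
  if (any(variances < 0)) stop("variances must be non-negative")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  if (b > 0) {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  } else {
    df <- Inf
  }
  se <- sqrt(total)
  stat <- if (total > 0) (qbar - theta0) / se else NA_real_
  p <- if (is.na(stat)) NA_real_
       else if (is.finite(df)) 2 * stats::pt(-abs(stat), df)
       else 2 * stats::pnorm(-abs(stat))
  structure(list(estimate = qbar, se = se, within = w, between = b,
                 total = total, df = df, statistic = stat, p.value = p, m = m),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled over %d imputations: estimate %.4g (SE %.4g), df %.4g, p %.4g\n",
              x$m, x$estimate, x$se, x$df, x$p.value))
  invisible(x)
}

#' Pooled confidence interval
#'
#' @param object A `pooled_result`.
#' @param parm Ignored (single parameter).
#' @param level Confidence level.
#' @param ... Ignored.
#' @return Numeric length-2 vector (lower, upper).
#' @export
confint.pooled_result <- function(object, parm, level = 0.95, ...) {
  q <- if (is.finite(object$df)) stats::qt(1 - (1 - level) / 2, object$df)
       else stats::qnorm(1 - (1 - level) / 2)
  c(object$estimate - q * object$se, object$estimate + q * object$se)
}

#' Pool a table of per-imputation parameter estimates
#'
#' Applies [rubin_pool()] row-wise to matrices of estimates and squared
#' standard errors with one column per imputation.
#'
#' @param est_matrix Numeric matrix, parameters x imputations.
#' @param var_matrix Matching matrix of squared standard errors.
#' @return Data frame with one row per parameter: `parameter`, `estimate`,
#'   `se`, `df`, `statistic`, `p.value`, `stars`.
#' @export
pool_parameter_table <- function(est_matrix, var_matrix) {
  stopifnot(all(dim(est_matrix) == dim(var_matrix)))
  rows <- lapply(seq_len(nrow(est_matrix)), function(i) {
    pr <- rubin_pool(est_matrix[i, ], var_matrix[i, ])
    data.frame(parameter = rownames(est_matrix)[i] %||% paste0("p", i),
               estimate = pr$estimate, se = pr$se, df = pr$df,
               statistic = pr$statistic, p.value = pr$p.value,
               stars = significance_stars(pr$p.value))
  })
  do.call(rbind, rows)
}

#' Significance stars
#'
#' Star bins used in the parameter tables: `***` for p < 0.0001, `**` for
#' 0.0001 <= p < 0.001, `*` for 0.001 <= p < 0.05, empty otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.001] <- "**"
  out[!is.na(p) & p < 0.0001] <- "***"
  out[is.na(p)] <- ""
  out
}
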