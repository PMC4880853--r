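# Fixed covariate block shared by all model variants, in equation order.
covariate_block <- function(data) {
  cbind(
    beta_q = log10(recode_water_consumption(data$tap_water_consumption)),
    beta_c = log10(data$creatinine),
    beta_f = as.numeric(data$gender == "female"),
    beta_b = log10(data$bmi),
    beta_a = log10(data$age),
    beta_s = log10(data$cotinine),
    beta_r = as.numeric(data$recent_fish))
}

source_dummies <- function(data) {
  D <- vapply(water_sources(), function(s) as.numeric(data$water_source == s),
              numeric(nrow(data)))
  colnames(D) <- paste0("alpha_", water_sources())
  D
}

# Design matrix for a fixed water transform `tw` (per-source intercepts,
# per-source slopes, covariates).
offset_design <- function(data, tw) {
  D <- source_dummies(data)
  S <- D * tw
  colnames(S) <- paste0("beta_", water_sources())
  cbind(D, S, covariate_block(data))
}

#' Fit the offset dose-response model to one completed dataset
#'
#' Non-linear least squares for
#' `Y = alpha_DWS + beta_DWS * log10(10^alpha_log_offset + WaterAs) +
#' beta_q log10(Q) + beta_c log10(Creatinine) + beta_f Female +
#' beta_b log10(BMI) + beta_a log10(Age) + beta_s log10(Cotinine) +
#' beta_r Fish`, with separate intercepts and slopes for the four
#' drinking-water source categories. For fixed `alpha_log_offset` the model
#' is linear, so the fit profiles the sum of squared residuals over
#' `alpha_log_offset`: a multi-start grid bounds the optimum, golden-section/
#' parabolic refinement plus a Newton polish locates it, and the linear
#' coefficients are the exact least-squares solution at the optimum.
#'
#' With `offset_enabled = FALSE` (used for relative-level and
#' methylation-index outcomes, where the offset was dropped from the model)
#' the water term is plain `log10(water_as)` and the fit is ordinary least
#' squares.
#'
#' The asymptotic covariance is the Gauss-Newton approximation
#' `sigma^2 (J'J)^{-1}` from the Jacobian at the optimum, which for the
#' linear case is exactly the OLS covariance.
#'
#' @param data Completed dataset (one imputation), with positive `water_tas`.
#' @param dependent Name of the response column, one of
#'   [dependent_variables()].
#' @param offset_enabled Logical; defaults to `TRUE` for the four absolute
#'   concentration outcomes and `FALSE` otherwise.
#' @param grid Multi-start grid for `alpha_log_offset`.
#' @param refine_span Half-width of the refinement interval around the best
#'   grid point.
#' @return Object of class `offset_fit`: `coefficients` (named, equation
#'   order), `vcov`, `sigma` (residual SD), `sse`, `n`, `df.residual`,
#'   `dependent`, `offset_enabled`, `convergence` (grid and refinement
#'   diagnostics).
#' @export
fit_offset_model <- function(data, dependent = "log10_tias",
                             offset_enabled = dependent %in%
                               c("log10_tias", "log10_mma", "log10_dma", "log10_usas"),
                             grid = c(-1, 0, 0.5, 1, 1.5),
                             refine_span = 0.75) {
  if (!dependent %in% names(data))
    stop("dependent variable '", dependent, "' not found; run add_derived_variables()")
  y <- data[[dependent]]
  n <- length(y)
  if (anyNA(y) || anyNA(data$water_tas))
    stop("fit requires completed data with no missing values")
  if (any(table(factor(data$water_source, levels = water_sources())) < 2))
    stop("each water-source category needs at least two observations")

  if (!offset_enabled) {
    if (any(data$water_tas <= 0))
      stop("water arsenic must be positive when the offset term is disabled")
    X <- offset_design(data, log10(data$water_tas))
    fit <- stats::lm.fit(X, y)
    p <- ncol(X)
    res <- fit$residuals
    sse <- sum(res^2)
    sigma2 <- sse / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    vc <- sigma2 * XtXi
    dimnames(vc) <- list(colnames(X), colnames(X))
    return(structure(list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
                          vcov = vc, sigma = sqrt(sigma2), sse = sse, n = n,
                          df.residual = n - p, dependent = dependent,
                          offset_enabled = FALSE,
                          convergence = list(method = "ols")),
                     class = "offset_fit"))
  }

  W <- data$water_tas
  sse_at <- function(a) {
    X <- offset_design(data, transform_water_as(W, a))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  sse_grid <- vapply(grid, sse_at, numeric(1))
  a0 <- grid[which.min(sse_grid)]
  opt <- stats::optimize(sse_at, interval = c(a0 - refine_span, a0 + refine_span),
                         tol = 1e-10)
  a <- opt$minimum
  # Newton polish on the profiled SSE
  h <- 1e-5
  for (i in 1:4) {
    f1 <- sse_at(a + h); f0 <- sse_at(a); f2 <- sse_at(a - h)
    g <- (f1 - f2) / (2 * h)
    hess <- (f1 - 2 * f0 + f2) / h^2
    if (!is.finite(hess) || hess <= 0) break
    step <- g / hess
    if (!is.finite(step) || abs(step) > refine_span) break
    a <- a - step
    if (abs(step) < 1e-12) break
  }
  tw <- transform_water_as(W, a)
  X <- offset_design(data, tw)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  p <- ncol(X) + 1L
  sigma2 <- sse / (n - p)
  # Jacobian of the mean wrt (alphas, betas, alpha_log_offset, covariates)
  D <- source_dummies(data)
  slope_per_row <- drop(D %*% beta[paste0("beta_", water_sources())])
  dfda <- slope_per_row * (10^a / (10^a + W))
  J <- cbind(X[, 1:8, drop = FALSE], alpha_log_offset = dfda,
             X[, 9:ncol(X), drop = FALSE])
  vc <- sigma2 * chol2inv(chol(crossprod(J)))
  dimnames(vc) <- list(colnames(J), colnames(J))
  coefs <- c(beta[1:8], alpha_log_offset = a, beta[9:length(beta)])
  names(coefs) <- colnames(J)
  structure(list(coefficients = coefs, vcov = vc, sigma = sqrt(sigma2),
                 sse = sse, n = n, df.residual = n - p, dependent = dependent,
                 offset_enabled = TRUE,
                 convergence = list(method = "profiled-ls", grid = grid,
                                    sse_grid = sse_grid,
                                    alpha_opt = a, sse_opt = sse)),
            class = "offset_fit")
}

#' @export
print.offset_fit <- function(x, ...) {
  cat(sprintf("Offset dose-response fit for %s (n = %d, offset %s)\n",
              x$dependent, x$n, if (x$offset_enabled) "estimated" else "disabled"))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  invisible(x)
}

#' Convert a fitted coefficient vector to `model_parameters`
#'
#' @param coefs Named coefficients as produced by [fit_offset_model()] (or a
#'   pooled table's estimate column named the same way).
#' @param offset_enabled Whether the water offset term is present.
#' @return A [model_parameters()] object.
#' @export
coef_to_parameters <- function(coefs, offset_enabled = "alpha_log_offset" %in% names(coefs)) {
  src <- water_sources()
  model_parameters(
    alpha = stats::setNames(coefs[paste0("alpha_", src)], src),
    beta = stats::setNames(coefs[paste0("beta_", src)], src),
    alpha_log_offset = if (offset_enabled) coefs[["alpha_log_offset"]] else NA_real_,
    beta_q = coefs[["beta_q"]], beta_c = coefs[["beta_c"]],
    beta_f = coefs[["beta_f"]], beta_b = coefs[["beta_b"]],
    beta_a = coefs[["beta_a"]], beta_s = coefs[["beta_s"]],
    beta_r = coefs[["beta_r"]], offset_enabled = offset_enabled)
}

#' Fit the model to every imputed dataset and pool by Rubin's rules
#'
#' @param mi An `mi_cohort` with derived columns.
#' @param dependent Response column name.
#' @param ... Passed to [fit_offset_model()].
#' @return List with `fits` (per-imputation `offset_fit`s) and `pooled`
#'   (data frame from [pool_parameter_table()]).
#' @export
fit_pooled_model <- function(mi, dependent = "log10_tias", ...) {
  fits <- lapply(mi$datasets, fit_offset_model, dependent = dependent, ...)
  est <- vapply(fits, function(f) f$coefficients, fits[[1]]$coefficients)
  vars <- vapply(fits, function(f) diag(f$vcov), fits[[1]]$coefficients)
  est <- matrix(est, ncol = mi$m,
                dimnames = list(names(fits[[1]]$coefficients), NULL))
  vars <- matrix(vars, ncol = mi$m, dimnames = dimnames(est))
  list(fits = fits, pooled = pool_parameter_table(est, vars))
}

#' Predicted dose-response curves at cohort-mean covariates
#'
#' Evaluates the fitted model along a grid of water arsenic concentrations
#' for each drinking-water source, holding gender and the log10-transformed
#' continuous covariates at their means across the supplied dataset — the
#' construction behind predicted concentration-vs-exposure curves.
#'
#' @param params A [model_parameters()] object (e.g. from
#'   [coef_to_parameters()] on pooled estimates).
#' @param data Completed dataset supplying covariate means.
#' @param water_grid Water arsenic grid, ug/L.
#' @return Data frame with `water_source`, `water_tas`, `predicted`
#'   (log10/logit scale) and `predicted_linear` (back-transformed via
#'   `10^predicted`).
#' @export
predict_curve <- function(params, data, water_grid = 10^seq(0, log10(1850), length.out = 50)) {
  mean_row <- data.frame(
    tap_water_consumption = 10^mean(log10(recode_water_consumption(data$tap_water_consumption))),
    creatinine = 10^mean(log10(data$creatinine)),
    gender = "male", bmi = 10^mean(log10(data$bmi)),
    age = 10^mean(log10(data$age)), cotinine = 10^mean(log10(data$cotinine)),
    recent_fish = mean(data$recent_fish))
  # gender enters as its mean proportion female, not a hard category
  female_mean <- mean(data$gender == "female")
  out <- do.call(rbind, lapply(water_sources(), function(s) {
    nd <- mean_row[rep(1, length(water_grid)), , drop = FALSE]
    nd$water_source <- s
    nd$water_tas <- water_grid
    pred <- predict_response(params, nd) + params$beta_f * female_mean
    data.frame(water_source = s, water_tas = water_grid, predicted = pred,
               predicted_linear = 10^pred)
  }))
  rownames(out) <- NULL
  out
}
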