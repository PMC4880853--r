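#' Fit a left-censored log-normal (Tobit) model
#'
#' Maximum-likelihood fit of a normal linear model on log10 concentrations in
#' which non-detect observations contribute the probability mass below their
#' detection limit. Concentrations are assumed log-normally distributed, with
#' the non-detect samples resembling the portion of the distribution below
#' the LOD. With no censoring the fit coincides with ordinary least squares
#' on the log10 values (maximum-likelihood variance, divisor n).
#'
#' Fitting is delegated to [survival::survreg()] with a Gaussian
#' distribution and left-censored response, the standard Tobit formulation.
#'
#' @param values Concentrations; non-detect entries must carry their LOD.
#' @param nd Logical non-detect flags, same length as `values`.
#' @param covariates Optional data.frame or matrix of covariates (numeric
#'   columns); `NULL` fits an intercept-only model.
#' @param weights Optional positive case weights.
#' @return Object of class `censored_fit` with elements `coefficients`,
#'   `sigma` (residual SD on log10 scale), `var` (asymptotic covariance of
#'   `(coefficients, log sigma)`), `n`, `n_censored`, `loglik`.
#' @export
fit_censored_lognormal <- function(values, nd, covariates = NULL,
                                   weights = NULL) {
  stopifnot(length(values) == length(nd))
  if (any(values <= 0, na.rm = TRUE))
    stop("concentrations must be strictly positive (non-detects carry their LOD)")
  keep <- !is.na(values) & !is.na(nd)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  y <- log10(values[keep])
  ev <- as.numeric(!nd[keep])
  if (sum(ev) < 1)
    stop("cannot fit: all values are below the detection limit")
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("weights must be strictly positive")
    weights <- weights[keep]
  }
  if (is.null(covariates)) {
    dat <- data.frame(.y = y, .ev = ev)
    fml <- survival::Surv(.y, .ev, type = "left") ~ 1
  } else {
    dat <- cbind(data.frame(.y = y, .ev = ev), covariates[keep, , drop = FALSE])
    fml <- stats::reformulate(colnames(covariates),
                              response = quote(survival::Surv(.y, .ev, type = "left")))
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  fit <- withCallingHandlers(
    survival::survreg(fml, data = dat, weights = .w, dist = "gaussian",
                      control = survival::survreg.control(maxiter = 200)),
    warning = function(w) {
      if (grepl("iterations", conditionMessage(w)))
        stop("censored log-normal fit did not converge: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  structure(
    list(coefficients = stats::coef(fit),
         sigma = fit$scale,
         var = fit$var,  # covariance of (coefficients, log sigma)
         n = length(y), n_censored = sum(nd[keep]),
         loglik = fit$loglik[2],
         covariate_names = if (is.null(covariates)) character(0) else colnames(covariates)),
    class = "censored_fit")
}

#' @export
print.censored_fit <- function(x, ...) {
  cat(sprintf("Left-censored log-normal fit: n = %d (%d non-detects)\n",
              x$n, x$n_censored))
  print(round(c(x$coefficients, sigma = x$sigma), 4))
  invisible(x)
}

# Draw (coefficients, sigma) from the asymptotic distribution of a
# censored_fit, for proper multiple imputation.
draw_censored_params <- function(fit) {
  est <- c(fit$coefficients, log(fit$sigma))
  draw <- MASS::mvrnorm(1, est, fit$var)
  k <- length(fit$coefficients)
  list(coefficients = draw[seq_len(k)], sigma = exp(draw[k + 1]))
}

# Draw (coefficients, sigma) for an OLS fit used for missing-covariate
# imputation: sigma^2 from scaled inverse chi-square, coefficients from
# their conditional normal.
draw_lm_params <- function(fit) {
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  sigma2 <- s2 * fit$df.residual / stats::rchisq(1, fit$df.residual)
  V <- stats::vcov(fit) / s2 * sigma2
  beta <- MASS::mvrnorm(1, stats::coef(fit), V)
  list(coefficients = beta, sigma = sqrt(sigma2))
}

# Inverse-CDF draw from a log10-normal truncated above at the LOD:
# strictly positive and strictly below lod.
rtrunc_below_lod <- function(mu, sigma, lod) {
  p_upper <- stats::pnorm((log10(lod) - mu) / sigma)
  u <- pmax(p_upper * stats::runif(length(mu)), 1e-300)
  val <- 10^(mu + sigma * stats::qnorm(u))
  pmin(pmax(val, lod * 1e-15), lod * (1 - 1e-12))
}

# Imputation-model design matrices. `species_before` lists analytes imputed
# earlier in the fixed order; their (proxy or completed) log10 values enter
# as covariates so imputation preserves inter-analyte correlations.
imputation_design <- function(data, species_before = character(0)) {
  X <- data.frame(
    log10_water = log10(data$water_tas),
    female = as.numeric(data$gender == "female"),
    log10_age = log10(data$age),
    log10_bmi = log10(data$bmi),
    log10_creatinine = log10(data$creatinine),
    src_filtered = as.numeric(data$water_source == "filtered"),
    src_other_treatment = as.numeric(data$water_source == "other_treatment"),
    src_bottled = as.numeric(data$water_source == "bottled"))
  for (sp in species_before) X[[paste0("log10_", sp)]] <- log10(data[[sp]])
  X
}

# The fixed sequential-imputation order for censored analytes.
imputation_order <- function() c("dma", "mma", "ias3", "ias5")

#' Fit the conditional models used for imputation
#'
#' Fits, on the observed cohort: an intercept-only censored log-normal model
#' for water arsenic; ordinary regressions of log10 BMI, creatinine and
#' cotinine on gender and log10 age (for the few missing covariate cells);
#' and censored log-normal models for each urinary analyte and toenail
#' arsenic, conditioning on water arsenic, gender, age, BMI, water source,
#' creatinine and the log10 values of analytes earlier in the fixed order
#' DMA, MMA, iAs3, iAs5, nails. Censored conditioning values enter at their
#' LOD.
#'
#' @param cohort Cohort data frame from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @return Named list of fitted models (class `imputation_models`).
#' @export
fit_imputation_models <- function(cohort) {
  models <- list()
  models$water_tas <- fit_censored_lognormal(cohort$water_tas, cohort$water_tas_nd)
  base <- data.frame(female = as.numeric(cohort$gender == "female"),
                     log10_age = log10(cohort$age))
  for (v in c("bmi", "creatinine", "cotinine")) {
    dat <- cbind(base, .y = log10(cohort[[v]]))
    models[[v]] <- stats::lm(.y ~ female + log10_age, data = dat,
                             na.action = stats::na.omit)
  }
  order <- imputation_order()
  for (i in seq_along(order)) {
    sp <- order[i]
    X <- imputation_design(cohort, species_before = order[seq_len(i - 1)])
    models[[sp]] <- fit_censored_lognormal(cohort[[sp]], cohort[[paste0(sp, "_nd")]],
                                           covariates = X)
  }
  Xn <- imputation_design(cohort, species_before = order)
  obs_nail <- !is.na(cohort$nail_tas)
  models$nail_tas <- fit_censored_lognormal(
    cohort$nail_tas[obs_nail], cohort$nail_tas_nd[obs_nail],
    covariates = Xn[obs_nail, , drop = FALSE])
  class(models) <- "imputation_models"
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiply impute non-detects and missing values
#'
#' Creates `m` completed copies of the cohort. Each below-LOD cell is filled
#' by an inverse-CDF draw from its fitted conditional log-normal truncated
#' above at the LOD; missing covariate and toenail cells are drawn from
#' fitted conditional models. Before every imputation the model parameters
#' are themselves drawn from their asymptotic distribution, so the completed
#' datasets reflect estimation uncertainty (proper multiple imputation).
#' Analytes are completed in the fixed order water, (BMI, creatinine,
#' cotinine), DMA, MMA, iAs3, iAs5, toenails, each conditioning on the
#' already-completed values, which maintains correlations among analysis
#' variables. Deterministic given `seed`.
#'
#' @param cohort Cohort data frame with `<analyte>`/`<analyte>_nd` pairs.
#' @param params Fitted [fit_imputation_models()] list; refitted on `cohort`
#'   when `NULL`.
#' @param m Number of imputations (default 20).
#' @param seed Integer seed.
#' @return Object of class `mi_cohort`: list with `datasets` (list of `m`
#'   completed data frames, each passed through [add_derived_variables()]),
#'   `provenance` (data frame of imputed cells: `m`, `row`, `column`,
#'   `reason`), and `m`.
#' @export
impute_nondetects <- function(cohort, params = NULL, m = 20, seed = 1) {
  if (m < 2) stop("m must be at least 2 for multiple imputation")
  cohort <- as.data.frame(cohort)
  nd_cols <- c("water_tas", "dma", "mma", "ias3", "ias5", "nail_tas")
  any_nd <- any(vapply(nd_cols, function(v) any(cohort[[paste0(v, "_nd")]], na.rm = TRUE),
                       logical(1)))
  any_miss <- anyNA(cohort[c("bmi", "creatinine", "cotinine", "nail_tas")])
  if (!any_nd && !any_miss) {
    completed <- add_derived_variables(strip_nd_flags(cohort))
    return(structure(list(datasets = rep(list(completed), m),
                          provenance = data.frame(m = integer(0), row = integer(0),
                                                  column = character(0),
                                                  reason = character(0)),
                          m = m),
                     class = "mi_cohort"))
  }
  if (is.null(params)) params <- fit_imputation_models(cohort)
  set.seed(seed)
  datasets <- vector("list", m)
  prov <- list()
  order <- imputation_order()
  for (im in seq_len(m)) {
    d <- cohort
    rec <- function(rows, col, reason) {
      if (length(rows))
        prov[[length(prov) + 1]] <<- data.frame(m = im, row = rows, column = col,
                                                reason = reason)
    }
    # water arsenic: intercept-only truncated draws at the per-cell LOD
    wnd <- which(d$water_tas_nd)
    if (length(wnd)) {
      pw <- draw_censored_params(params$water_tas)
      d$water_tas[wnd] <- rtrunc_below_lod(rep(pw$coefficients[1], length(wnd)),
                                           pw$sigma, d$water_tas[wnd])
      d$water_tas_nd[wnd] <- FALSE
      rec(wnd, "water_tas", "nondetect")
    }
    # missing covariates from conditional normal models
    base <- data.frame(1, as.numeric(d$gender == "female"), log10(d$age))
    for (v in c("bmi", "creatinine", "cotinine")) {
      miss <- which(is.na(d[[v]]))
      if (length(miss)) {
        pv <- draw_lm_params(params[[v]])
        mu <- as.matrix(base[miss, , drop = FALSE]) %*% pv$coefficients
        d[[v]][miss] <- 10^(mu + pv$sigma * stats::rnorm(length(miss)))
        rec(miss, v, "missing")
      }
    }
    # urinary species, sequentially, conditioning on completed predecessors
    for (i in seq_along(order)) {
      sp <- order[i]
      ndx <- which(d[[paste0(sp, "_nd")]])
      if (length(ndx)) {
        ps <- draw_censored_params(params[[sp]])
        X <- cbind(1, as.matrix(imputation_design(d, order[seq_len(i - 1)])))
        mu <- drop(X[ndx, , drop = FALSE] %*% ps$coefficients)
        d[[sp]][ndx] <- rtrunc_below_lod(mu, ps$sigma, d[[sp]][ndx])
        d[[paste0(sp, "_nd")]][ndx] <- FALSE
        rec(ndx, sp, "nondetect")
      }
    }
    # toenails: truncated draws for non-detects, unconditional normal draws
    # for missing records
    pn <- draw_censored_params(params$nail_tas)
    Xn <- cbind(1, as.matrix(imputation_design(d, order)))
    mun <- drop(Xn %*% pn$coefficients)
    nnd <- which(!is.na(d$nail_tas_nd) & d$nail_tas_nd)
    if (length(nnd)) {
      d$nail_tas[nnd] <- rtrunc_below_lod(mun[nnd], pn$sigma, d$nail_tas[nnd])
      d$nail_tas_nd[nnd] <- FALSE
      rec(nnd, "nail_tas", "nondetect")
    }
    nmiss <- which(is.na(d$nail_tas))
    if (length(nmiss)) {
      d$nail_tas[nmiss] <- 10^(mun[nmiss] + pn$sigma * stats::rnorm(length(nmiss)))
      d$nail_tas_nd[nmiss] <- FALSE
      rec(nmiss, "nail_tas", "missing")
    }
    datasets[[im]] <- add_derived_variables(strip_nd_flags(d))
  }
  structure(list(datasets = datasets,
                 provenance = if (length(prov)) do.call(rbind, prov)
                              else data.frame(m = integer(0), row = integer(0),
                                              column = character(0),
                                              reason = character(0)),
                 m = m),
            class = "mi_cohort")
}

# After completion no censoring flags remain meaningful; drop them.
strip_nd_flags <- function(d) {
  d[grep("_nd$", names(d))] <- NULL
  d
}

#' @export
print.mi_cohort <- function(x, ...) {
  cat(sprintf("Multiply-imputed cohort: m = %d datasets, %d rows, %d imputed cells\n",
              x$m, nrow(x$datasets[[1]]), nrow(x$provenance) / max(x$m, 1)))
  invisible(x)
}

#' Write the completed datasets of an `mi_cohort` to CSV files
#'
#' @param mi An `mi_cohort` object.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; files are `<prefix>_m<k>.csv` plus
#'   `<prefix>_provenance.csv`.
#' @return Character vector of written paths, invisibly.
#' @export
write_mi_csv <- function(mi, dir, prefix = "imputed") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (im in seq_len(mi$m)) {
    p <- file.path(dir, sprintf("%s_m%02d.csv", prefix, im))
    utils::write.csv(mi$datasets[[im]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  pp <- file.path(dir, paste0(prefix, "_provenance.csv"))
  utils::write.csv(mi$provenance, pp, row.names = FALSE)
  invisible(c(paths, pp))
}
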