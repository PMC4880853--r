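test_that("with no censoring the fit reduces to the complete-data MLE", {
  set.seed(1)
  x <- 10^rnorm(500, 0.8, 0.3)
  fit <- fit_censored_lognormal(x, nd = rep(FALSE, 500))
  lx <- log10(x)
  expect_equal(unname(fit$coefficients[1]), mean(lx), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(mean((lx - mean(lx))^2)), tolerance = 1e-4)
  # with covariates: coincides with ordinary least squares on log10 values
  z <- rnorm(500)
  y <- 10^(0.5 + 0.4 * z + rnorm(500, 0, 0.2))
  fitc <- fit_censored_lognormal(y, rep(FALSE, 500), covariates = data.frame(z = z))
  ols <- lm(log10(y) ~ z)
  expect_equal(unname(fitc$coefficients), unname(coef(ols)), tolerance = 1e-6)
})

test_that("censored fits recover known parameters within 3 SEs", {
  # 30% censoring at n = 2000
  set.seed(2)
  n <- 2000; mu <- 0.6; sig <- 0.5
  lod <- 10^(mu + sig * qnorm(0.3))
  x <- 10^rnorm(n, mu, sig)
  cens <- apply_censoring(x, lod)
  fit <- fit_censored_lognormal(cens$value, cens$nd)
  se_mu <- sqrt(fit$var[1, 1])
  expect_lt(abs(fit$coefficients[1] - mu), 3 * se_mu)
  expect_lt(abs(fit$sigma - sig) / sig, 0.15)
  expect_equal(fit$n_censored, sum(cens$nd))

  # heavy censoring (the iAs(V)-like 64% rate) at n = 904 still converges
  set.seed(3)
  n <- 904
  lod64 <- 10^(mu + sig * qnorm(0.64))
  x <- 10^rnorm(n, mu, sig)
  cens <- apply_censoring(x, lod64)
  expect_gt(mean(cens$nd), 0.55)
  fit <- fit_censored_lognormal(cens$value, cens$nd)
  expect_lt(abs(fit$coefficients[1] - mu), 3 * sqrt(fit$var[1, 1]))
})

test_that("degenerate censoring inputs raise estimation errors", {
  expect_error(fit_censored_lognormal(c(1, 1, 1), nd = c(TRUE, TRUE, TRUE)),
               "below the detection limit")
  expect_error(fit_censored_lognormal(c(0, 1), nd = c(FALSE, FALSE)),
               "strictly positive")
})

test_that("a cohort with nothing to impute yields m identical copies", {
  cfg <- no_missing_config(n_participants = 60, truth = null_truth(),
                           water_meanlog10 = 2.2, water_sdlog10 = 0.2,
                           ias3_frac_conc = 50, nail_intercept = 0,
                           target_gm = c(tias = 100, mma = 100, dma = 200))
  coh <- generate_cohort(cfg, seed = 7)
  # high geometric means push everything above the LODs
  expect_false(any(coh$ias5_nd | coh$ias3_nd | coh$mma_nd | coh$dma_nd |
                     coh$water_tas_nd | coh$nail_tas_nd))
  mi <- impute_nondetects(coh, m = 4, seed = 1)
  expect_equal(mi$m, 4)
  expect_identical(mi$datasets[[1]], mi$datasets[[4]])
  expect_equal(nrow(mi$provenance), 0L)
})

test_that("default pipeline produces 20 completed datasets with valid imputations", {
  cfg <- smoke_config(n = 150)
  coh <- generate_cohort(cfg, seed = 8)
  mi <- impute_nondetects(coh, m = 20, seed = 9)
  expect_equal(mi$m, 20)
  expect_length(mi$datasets, 20)
  lods <- cfg$urine_lods
  for (im in c(1, 10, 20)) {
    d <- mi$datasets[[im]]
    expect_false(anyNA(d[c("ias3", "ias5", "mma", "dma", "water_tas",
                           "nail_tas", "bmi", "cotinine", "creatinine")]))
    for (sp in names(lods)) {
      ndx <- which(coh[[paste0(sp, "_nd")]])
      expect_true(all(d[[sp]][ndx] > 0 & d[[sp]][ndx] < lods[[sp]]))
      # detected cells pass through untouched
      det <- which(!coh[[paste0(sp, "_nd")]])
      expect_identical(d[[sp]][det], coh[[sp]][det])
    }
  }
  # proper imputation: between-imputation variability of imputed cells
  ndx <- which(coh$ias5_nd)
  vals <- sapply(mi$datasets, function(d) d$ias5[ndx])
  expect_true(all(apply(vals, 1, stats::sd) > 0))
  # deterministic given seed
  mi2 <- impute_nondetects(coh, m = 20, seed = 9)
  expect_identical(mi$datasets[[20]], mi2$datasets[[20]])
})

test_that("mean of imputed non-detects matches the quadrature truncated mean", {
  cfg <- smoke_config(n = 2000)
  coh <- generate_cohort(cfg, seed = 10)
  params <- fit_imputation_models(coh)
  m <- 10
  mi <- impute_nondetects(coh, params = params, m = m, seed = 11)
  # oracle: per-cell E[X | X < LOD] under the fitted conditional model,
  # by numerical integration of the truncated log-normal
  fit <- params$dma
  X <- cbind(1, as.matrix(asmet:::imputation_design(coh, character(0))))
  ndx <- which(coh$dma_nd)
  mu_i <- drop(X[ndx, , drop = FALSE] %*% fit$coefficients)
  lod <- cfg$urine_lods[["dma"]]
  oracle <- vapply(mu_i, function(mu) {
    zf <- function(t) 10^t * dnorm(t, mu, fit$sigma)
    stats::integrate(zf, mu - 8 * fit$sigma, log10(lod))$value /
      pnorm((log10(lod) - mu) / fit$sigma)
  }, numeric(1))
  per_imp_mean <- vapply(mi$datasets, function(d) mean(d$dma[ndx]), numeric(1))
  se <- stats::sd(per_imp_mean) / sqrt(m)
  expect_lt(abs(mean(per_imp_mean) - mean(oracle)), 3 * se)
})

test_that("imputation preserves inter-analyte correlations", {
  cfg <- smoke_config(n = 2000)
  coh <- generate_cohort(cfg, seed = 12)
  lat <- attr(coh, "latent")
  r_true <- cor(log10(lat$mma), log10(lat$dma))
  mi <- impute_nondetects(coh, m = 5, seed = 13)
  r_imp <- mean(vapply(mi$datasets,
                       function(d) cor(log10(d$mma), log10(d$dma)), numeric(1)))
  expect_lt(abs(r_imp - r_true), 0.1)
  # the heavily censored species too
  r_true5 <- cor(log10(lat$ias5), log10(lat$dma))
  r_imp5 <- mean(vapply(mi$datasets,
                        function(d) cor(log10(d$ias5), log10(d$dma)), numeric(1)))
  expect_lt(abs(r_imp5 - r_true5), 0.1)
})

test_that("completed datasets can be written to CSV", {
  cfg <- smoke_config(n = 40)
  coh <- generate_cohort(cfg, seed = 14)
  mi <- impute_nondetects(coh, m = 2, seed = 15)
  dir <- withr::local_tempdir()
  paths <- write_mi_csv(mi, dir)
  files <- list.files(dir)
  expect_length(grep("^imputed_m", files), 2)
  expect_true("imputed_provenance.csv" %in% files)
  back <- utils::read.csv(file.path(dir, "imputed_m01.csv"))
  expect_false(anyNA(back$ias5))
})
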