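test_that("the water transform has the stated limits and monotonicity", {
  expect_equal(transform_water_as(0, 1.2), 1.2)
  expect_equal(transform_water_as(99, 0), 2)
  grid <- seq(0, 1850, length.out = 500)
  for (a in c(-1, 0, 1.2)) {
    tw <- transform_water_as(grid, a)
    expect_true(all(diff(tw) > 0))
  }
  expect_error(transform_water_as(-1, 0), "non-negative")
})

test_that("noiseless data reproduce the generating parameters to 1e-6", {
  cfg <- no_missing_config(n_participants = 904,
                           residual_sd = c(tias = 0, mma = 0, dma = 0))
  d <- completed_from_latent(cfg, seed = 50)
  for (sp in c("tias", "dma")) {
    fit <- fit_offset_model(d, paste0("log10_", sp))
    tr <- cfg$truth[[sp]]
    tru <- c(tr$alpha, tr$beta, alpha_log_offset = tr$alpha_log_offset,
             beta_q = tr$beta_q, beta_c = tr$beta_c, beta_f = tr$beta_f,
             beta_b = tr$beta_b, beta_a = tr$beta_a, beta_s = tr$beta_s,
             beta_r = tr$beta_r)
    expect_lt(max(abs(fit$coefficients - tru)), 1e-6)
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("with the offset disabled the fit equals the linear least-squares oracle", {
  cfg <- no_missing_config(n_participants = 400)
  d <- completed_from_latent(cfg, seed = 51)
  fit <- fit_offset_model(d, "logit_pct_mma", offset_enabled = FALSE)
  # independent oracle: lm() on the explicitly constructed design
  dd <- d
  dd$src <- factor(dd$water_source, levels = water_sources())
  dd$lw <- log10(dd$water_tas)
  ora <- lm(logit_pct_mma ~ 0 + src + src:lw +
              log10(recode_water_consumption(tap_water_consumption)) +
              log10(creatinine) + I(gender == "female") + log10(bmi) +
              log10(age) + log10(cotinine) + recent_fish, data = dd)
  co <- coef(ora)
  ora_named <- c(co[paste0("src", water_sources())],
                 co[paste0("src", water_sources(), ":lw")],
                 co[setdiff(names(co), c(paste0("src", water_sources()),
                                         paste0("src", water_sources(), ":lw")))])
  expect_lt(max(abs(unname(fit$coefficients) - unname(ora_named))), 1e-8)
  # standard errors agree with the OLS oracle too
  se_fit <- sqrt(diag(fit$vcov))
  se_ora <- sqrt(diag(vcov(ora)))[names(ora_named)]
  expect_lt(max(abs(unname(se_fit) - unname(se_ora))), 1e-8)
})

test_that("profiled SSE is unimodal near the optimum and fits are order-invariant", {
  cfg <- no_missing_config(n_participants = 500)
  d <- completed_from_latent(cfg, seed = 52)
  fit <- fit_offset_model(d, "log10_tias")
  a_opt <- fit$coefficients[["alpha_log_offset"]]
  sse_at <- function(a) {
    X <- asmet:::offset_design(d, transform_water_as(d$water_tas, a))
    sum(stats::lm.fit(X, d$log10_tias)$residuals^2)
  }
  grid <- seq(a_opt - 0.6, a_opt + 0.6, length.out = 25)
  sses <- vapply(grid, sse_at, numeric(1))
  k <- which.min(abs(grid - a_opt))
  expect_true(all(diff(sses[1:k]) <= 1e-9))
  expect_true(all(diff(sses[k:length(sses)]) >= -1e-9))
  # row-order invariance
  perm <- sample(nrow(d))
  fit2 <- fit_offset_model(d[perm, ], "log10_tias")
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("predictions behave per the model structure", {
  src <- water_sources()
  flat <- model_parameters(alpha = stats::setNames(rep(0.7, 4), src),
                           beta = stats::setNames(rep(0, 4), src),
                           alpha_log_offset = 1)
  nd <- data.frame(water_source = "untreated", water_tas = c(1, 100, 1000),
                   tap_water_consumption = 1, creatinine = 100, gender = "male",
                   bmi = 28, age = 60, cotinine = 3, recent_fish = 0)
  expect_equal(predict_response(flat, nd), rep(0.7, 3))
  expect_error(predict_response(flat, transform(nd, water_source = "well")),
               "unknown water source")
  # offset damping: a large offset flattens the low-dose response
  damp <- function(a) {
    p <- model_parameters(alpha = stats::setNames(rep(0, 4), src),
                          beta = stats::setNames(rep(1, 4), src),
                          alpha_log_offset = a)
    pr <- predict_response(p, nd[1:2, ])
    pr[2] - pr[1]   # change when water As goes 1 -> 100
  }
  expect_lt(damp(2), damp(-2))
  expect_equal(damp(-6), 2, tolerance = 1e-3)  # no offset: pure log10 change
  # prediction at generated covariates equals the generative mean
  cfg <- no_missing_config(n_participants = 100,
                           residual_sd = c(tias = 0, mma = 0, dma = 0))
  d <- completed_from_latent(cfg, seed = 53)
  expect_equal(predict_response(cfg$truth$mma, d), d$log10_mma, tolerance = 1e-12)
})

test_that("pooled confidence intervals cover the true untreated slope", {
  # joint calibration of generation, imputation, fitting and pooling on a
  # scaled problem: modest cohorts, m = 5
  cfg <- cohort_config(n_participants = 400)
  big <- no_missing_config(n_participants = 60000)
  dbig <- completed_from_latent(big, seed = 54)
  beta_true <- fit_offset_model(dbig, "log10_dma")$coefficients[["beta_untreated"]]
  nsim <- 25
  cover <- logical(nsim)
  for (s in seq_len(nsim)) {
    coh <- generate_cohort(cfg, seed = 800 + s)
    mi <- impute_nondetects(coh, m = 5, seed = 900 + s)
    pm <- fit_pooled_model(mi, "log10_dma")
    row <- pm$pooled[pm$pooled$parameter == "beta_untreated", ]
    qq <- stats::qt(0.975, row$df)
    cover[s] <- (row$estimate - qq * row$se <= beta_true) &&
      (beta_true <= row$estimate + qq * row$se)
  }
  expect_gte(mean(cover), 0.8)   # 95% nominal; wide band for 25 replicates
})

test_that("prediction curves run per source at cohort-mean covariates", {
  cfg <- no_missing_config(n_participants = 300)
  d <- completed_from_latent(cfg, seed = 55)
  curve <- predict_curve(cfg$truth$dma, d, water_grid = c(1, 10, 100))
  expect_equal(nrow(curve), 12)
  expect_setequal(unique(curve$water_source), water_sources())
  expect_true(all(tapply(curve$predicted, curve$water_source, function(x) all(diff(x) > 0))))
  expect_equal(curve$predicted_linear, 10^curve$predicted)
})
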