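test_that("censored weighted GM reduces to the ordinary GM and is weight-scale invariant", {
  set.seed(60)
  x <- 10^rnorm(200, 0.5, 0.3)
  res <- censored_weighted_gm(x, nd = rep(FALSE, 200))
  expect_equal(res$gm, 10^mean(log10(x)), tolerance = 1e-6)
  w <- runif(200, 0.5, 2)
  r1 <- censored_weighted_gm(x, rep(FALSE, 200), weights = w)
  r2 <- censored_weighted_gm(x, rep(FALSE, 200), weights = 2 * w)
  expect_equal(r1$gm, r2$gm, tolerance = 1e-8)
  expect_error(censored_weighted_gm(c(1, 1), c(TRUE, TRUE)), "below the detection")
})

test_that("censored weighted GM recovers known truth and is consistent", {
  mu <- 0.4; sig <- 0.5
  bias <- sapply(c(500, 5000), function(n) {
    set.seed(n)
    x <- 10^rnorm(n, mu, sig)
    cens <- apply_censoring(x, 10^(mu - 0.2))  # ~35% censored
    fit <- fit_censored_lognormal(cens$value, cens$nd)
    c(err = abs(fit$coefficients[[1]] - mu), se = sqrt(fit$var[1, 1]))
  })
  expect_lt(bias["err", 1], 3 * bias["se", 1])
  expect_lt(bias["err", 2], 3 * bias["se", 2])
  expect_lt(bias["err", 2], bias["err", 1])  # bias shrinks with n
})

test_that("post-stratification matches target shares and preserves total weight", {
  # fixed point: equal weights and target equal to the reference's own
  # distribution leave every weight unchanged
  ref <- data.frame(
    gender = rep(c("female", "male"), each = 40),
    race = "white",
    age = rep(c(47, 65, 65, 65), times = 20),
    weight = rep(1, 80))
  w_same <- reweight_reference(ref, ref)
  expect_equal(w_same, ref$weight, tolerance = 1e-12)
  # post-stratified cell shares match the target's shares exactly
  set.seed(66)
  ref_w <- transform(ref, weight = runif(80, 0.5, 2))
  target <- data.frame(gender = sample(c("female", "male"), 200, TRUE),
                       race = "white",
                       age = sample(c(47, 65), 200, TRUE))
  w_ps <- reweight_reference(ref_w, target)
  cells <- asmet:::demographic_cells(ref_w)
  shares <- tapply(w_ps, cells, sum) / sum(w_ps)
  tshare <- prop.table(table(asmet:::demographic_cells(target)))
  nz <- names(tshare)[tshare > 0]
  expect_equal(as.numeric(shares[nz]), as.numeric(tshare[nz]), tolerance = 1e-12)
  expect_equal(sum(w_ps), sum(ref_w$weight), tolerance = 1e-9)

  # hand-computed two-cell case: shares (1/4, 3/4) -> (1/2, 1/2)
  ref2 <- data.frame(gender = c("female", rep("male", 3)), race = "white",
                     age = 50, weight = rep(1, 4))
  target2 <- data.frame(gender = c("female", "male"), race = "white", age = 50)
  w2 <- reweight_reference(ref2, target2)
  expect_equal(w2, c(2, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(sum(w2), 4)

  # empty target cell in the reference is an error naming the cell
  target3 <- data.frame(gender = "female", race = "other", age = 85)
  expect_error(reweight_reference(ref2, target3), "no observations")
})

test_that("comparison table recovers an imposed GM shift and reports non-detects", {
  # null-truth cohort: species marginals are exactly log10-normal, so the
  # censored ML geometric means are unbiased and the shift oracle applies
  cfg <- cohort_config(n_participants = 800, truth = null_truth(),
                       target_gm = c(tias = 2, mma = 2, dma = 4))
  coh <- generate_cohort(cfg, seed = 61)
  mi <- impute_nondetects(coh, m = 3, seed = 62)
  ref <- generate_reference_survey(cfg, log10_shift = 0.5, seed = 63)
  tab <- compare_cohort_to_reference(mi, coh, ref)
  expect_setequal(tab$species, c("ias3", "ias5", "mma", "dma"))
  for (sp in c("mma", "dma"))
    expect_equal(tab$gm_ratio[tab$species == sp], 10^0.5, tolerance = 0.15)
  # the low-exposure reference has many more non-detects
  expect_true(all(tab$reference_nd_pct >= tab$cohort_nd_pct))
  expect_true(all(c("cohort_nd_pct", "reference_nd_pct",
                    "cohort_mean_lod", "reference_mean_lod") %in% names(tab)))
  expect_error(compare_cohort_to_reference(mi, coh, ref, species = c("dma", "asb")),
               "absent")
})

test_that("identical populations give unit ratios", {
  cfg <- cohort_config(n_participants = 400, truth = null_truth(),
                       water_meanlog10 = 2.2, water_sdlog10 = 0.2,
                       ias3_frac_conc = 50, nail_intercept = 0,
                       residual_sd = c(tias = 0.25, mma = 0.25, dma = 0.25),
                       target_gm = c(tias = 300, mma = 300, dma = 600))
  coh <- generate_cohort(cfg, seed = 64)
  # fully detected cohort: completed data equal observed data
  expect_false(any(coh$ias3_nd | coh$ias5_nd | coh$mma_nd | coh$dma_nd))
  mi <- impute_nondetects(coh, m = 2, seed = 65)
  ref <- as.data.frame(coh)
  ref$weight <- rep(1, nrow(ref))
  tab <- compare_cohort_to_reference(mi, coh, ref)
  expect_equal(tab$gm_ratio, rep(1, 4), tolerance = 1e-6)
})
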