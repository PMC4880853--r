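test_that("default cohort has the expected size, range and determinism", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(coh), 904L)
  expect_lte(max(attr(coh, "latent")$water_tas), 1850)
  coh2 <- generate_cohort(cfg, seed = 1)
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
  coh3 <- generate_cohort(cfg, seed = 2)
  expect_false(identical(coh$water_tas, coh3$water_tas))
})

test_that("generated records satisfy the record invariants across many seeds", {
  cfg <- smoke_config(n = 50)
  lods <- cfg$urine_lods
  for (s in 1:100) {
    coh <- generate_cohort(cfg, seed = s)
    num <- coh[c("age", "bmi", "water_tas", "tap_water_consumption", "cotinine",
                 "creatinine", "nail_tas", "ias3", "ias5", "mma", "dma")]
    expect_true(all(unlist(num) >= 0, na.rm = TRUE))
    expect_true(all(coh$age >= 45))
    expect_true(all(coh$water_source %in% water_sources()))
    # flagged below-LOD cells carry the LOD itself
    expect_true(all(coh$ias3[coh$ias3_nd] == lods[["ias3"]]))
    expect_true(all(coh$ias5[coh$ias5_nd] == lods[["ias5"]]))
    expect_true(all(coh$mma[coh$mma_nd] == lods[["mma"]]))
    expect_true(all(coh$dma[coh$dma_nd] == lods[["dma"]]))
    expect_true(all(coh$water_tas[coh$water_tas_nd] == cfg$water_lod))
    # detected cells lie at or above the LOD
    expect_true(all(coh$ias5[!coh$ias5_nd] >= lods[["ias5"]]))
  }
})

test_that("empirical covariate moments match the configured moments at n = 10,000", {
  n <- 10000
  cfg <- smoke_config(n = n)
  coh <- generate_cohort(cfg, seed = 3)
  # binomial-type covariates: within 3 Monte-Carlo SEs
  for (spec in list(c("female", cfg$female_prob), c("fish", cfg$fish_prob))) {
    p <- as.numeric(spec[2])
    emp <- if (spec[1] == "female") mean(coh$gender == "female") else mean(coh$recent_fish)
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
  # log-normal covariates: mean log10 within 3 SEs
  expect_lt(abs(mean(log10(coh$bmi), na.rm = TRUE) - cfg$bmi_meanlog10),
            3 * cfg$bmi_sdlog10 / sqrt(n))
  expect_lt(abs(mean(log10(coh$creatinine), na.rm = TRUE) - cfg$creatinine_meanlog10),
            3 * cfg$creatinine_sdlog10 / sqrt(n))
  # water source shares
  shares <- prop.table(table(coh$water_source))[water_sources()]
  for (s in water_sources()) {
    p <- cfg$water_source_probs[[s]]
    expect_lt(abs(shares[[s]] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("urinary non-detect fraction agrees with a Monte-Carlo estimate of the censoring probability", {
  cfg <- smoke_config(n = 10000)
  coh <- generate_cohort(cfg, seed = 11)
  # independent Monte-Carlo estimate from a second large draw of the same
  # configured generative model (latent values, before censoring)
  coh2 <- generate_cohort(cfg, seed = 12)
  for (sp in c("dma", "mma", "ias5")) {
    mc <- mean(attr(coh2, "latent")[[sp]] < cfg$urine_lods[[sp]])
    emp <- mean(coh[[paste0(sp, "_nd")]])
    expect_lt(abs(emp - mc), 0.02)
  }
})

test_that("zero residual SD reproduces the model mean structure exactly", {
  cfg <- no_missing_config(n_participants = 300,
                           residual_sd = c(tias = 0, mma = 0, dma = 0))
  coh <- generate_cohort(cfg, seed = 4)
  lat <- attr(coh, "latent")
  covars <- as.data.frame(coh)
  covars$water_tas <- lat$water_tas
  for (sp in c("tias", "mma", "dma")) {
    expect_equal(log10(lat[[sp]]), predict_response(cfg$truth[[sp]], covars),
                 tolerance = 1e-12)
  }
  # and the centered truth hits the target geometric mean at large n
  big <- generate_cohort(no_missing_config(n_participants = 20000,
                                           residual_sd = c(tias = 0, mma = 0, dma = 0)),
                         seed = 5)
  gm <- 10^mean(log10(attr(big, "latent")$dma))
  expect_lt(abs(gm - cohort_config()$target_gm[["dma"]]) / cohort_config()$target_gm[["dma"]], 0.05)
})

test_that("apply_censoring implements the non-detect rule", {
  out <- apply_censoring(c(0.4, 0.6), lod = 0.5)
  expect_equal(out$value, c(0.5, 0.6))
  expect_equal(out$nd, c(TRUE, FALSE))
  empty <- apply_censoring(numeric(0), lod = 1)
  expect_length(empty$value, 0)
  expect_error(apply_censoring(c(-1, 2), lod = 1), "non-negative")
  expect_error(apply_censoring(c(1, 2), lod = 0), "> 0")
  # non-detect fraction of a log-normal sample matches the normal-CDF oracle
  set.seed(99)
  x <- 10^rnorm(50000, 1, 1)
  frac <- mean(apply_censoring(x, 3)$nd)
  expect_lt(abs(frac - pnorm((log10(3) - 1) / 1)), 0.01)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(water_lod = -1), "water_lod")
  expect_error(cohort_config(water_source_probs = c(untreated = 0.5, filtered = 0.5,
                                                    other_treatment = 0.2, bottled = 0)),
               "water_source_probs")
  expect_error(cohort_config(age_range = c(30, 92)), "age_range")
  expect_error(cohort_config(female_prob = 1.2), "female_prob")
  expect_error(cohort_config(residual_cor = 2), "residual_cor")
})

test_that("cohort CSV round-trips through write/read", {
  cfg <- smoke_config(n = 40)
  coh <- generate_cohort(cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$water_tas, coh$water_tas)
  expect_equal(back$ias5_nd, coh$ias5_nd)
  expect_equal(back$gender, coh$gender)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(cfg$truth, tpath)
  tr <- utils::read.csv(tpath)
  expect_setequal(unique(tr$species), c("tias", "mma", "dma"))
  expect_equal(tr$value[tr$species == "tias" & tr$parameter == "beta_untreated"], 0.813)
})
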