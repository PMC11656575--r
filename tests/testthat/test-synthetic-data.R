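# Synthetic-data generator: determinism, truth-table semantics, and
# parameter recovery.

test_that("generation is bit-reproducible given the seed", {
  cfg <- sim_config(n_participants = 100, n_mediators = 50, seed = 7)
  s1 <- sim_study(cfg)
  s2 <- sim_study(cfg)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$stress_items, s2$stress_items)
  expect_identical(s1$methylation, s2$methylation)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$annotation, s2$annotation)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 0), class = "medewas_config_error")
  expect_error(sim_config(null_mix = c(0.5, 0.5, 0.1, 0.1)),
               class = "medewas_config_error")
  expect_error(sim_config(null_mix = c(1.2, -0.2, 0, 0)),
               class = "medewas_config_error")
  expect_error(sim_config(block_rho = 1), class = "medewas_config_error")
  expect_error(sim_config(noise_sd_mediator = 0),
               class = "medewas_config_error")
  cfg <- sim_config(n_participants = 10, n_mediators = 5)
  expect_error(sim_methylation(cfg, rnorm(7)),
               class = "medewas_dimension_error")
})

test_that("zero covariate correlation leaves exposure and age uncorrelated", {
  n <- 10000
  cfg <- sim_config(n_participants = n, n_mediators = 10,
                    exposure_covariate_cor = 0, seed = 11)
  cohort <- sim_cohort(cfg)
  r <- cor(cohort$phenotype$latent_stress, cohort$phenotype$age)
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("nonzero covariate correlation is realized at the configured level", {
  n <- 10000
  cfg <- sim_config(n_participants = n, n_mediators = 10,
                    exposure_covariate_cor = 0.3, seed = 12)
  cohort <- sim_cohort(cfg)
  r <- cor(cohort$phenotype$latent_stress, cohort$phenotype$age)
  expect_lt(abs(r - 0.3), 4 / sqrt(n))
})

test_that("pure complete-null mix yields an all-null truth table", {
  cfg <- sim_config(n_participants = 50, n_mediators = 400,
                    null_mix = c(1, 0, 0, 0), seed = 3)
  meth <- sim_methylation(cfg, rnorm(50))
  expect_true(all(meth$truth$true_alpha == 0))
  expect_true(all(meth$truth$true_beta == 0))
  expect_true(all(meth$truth$null_category == "H00"))
})

test_that("truth table is consistent and category counts match the mix", {
  cfg <- sim_config(n_participants = 50, n_mediators = 5000,
                    null_mix = c(0.7, 0.1, 0.1, 0.1), seed = 5)
  meth <- sim_methylation(cfg, rnorm(50))
  tr <- meth$truth
  expect_identical(tr$true_mediation_effect != 0, tr$null_category == "H11")
  counts <- table(factor(tr$null_category,
                         levels = c("H00", "H10", "H01", "H11")))
  expected <- cfg$null_mix * 5000
  sds <- sqrt(5000 * cfg$null_mix * (1 - cfg$null_mix))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("beta values stay in [0, 1] even under extreme settings", {
  cfg <- sim_config(n_participants = 80, n_mediators = 200,
                    alpha_effect = 0.8, beta_effect = 1,
                    noise_sd_mediator = 0.5, cell_effect_scale = 0.3,
                    null_mix = c(0, 0, 0, 1), seed = 9)
  meth <- sim_methylation(cfg, rnorm(80))
  expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  expect_gt(attr(meth$beta, "clip_rate"), 0)
})

test_that("cell proportion rows sum to one", {
  cfg <- sim_config(n_participants = 40, n_mediators = 10, seed = 2)
  meth <- sim_methylation(cfg, rnorm(40))
  expect_equal(rowSums(meth$cells), rep(1, 40), tolerance = 1e-12)
})

test_that("per-CpG OLS recovers alpha_effect on H11 mediators", {
  n <- 2000
  cfg <- sim_config(n_participants = n, n_mediators = 300,
                    null_mix = c(0, 0, 0, 1), alpha_effect = 0.05,
                    seed = 21)
  x <- rnorm(n)
  meth <- sim_methylation(cfg, x)
  alpha_hat <- as.numeric(crossprod(x - mean(x), scale(meth$beta,
                                                       scale = FALSE))) /
    sum((x - mean(x))^2)
  expect_lt(mean(abs(alpha_hat - 0.05)), 0.005)
})

test_that("H01 mediators give uniform exposure-path p-values", {
  n <- 200
  cfg <- sim_config(n_participants = n, n_mediators = 5000,
                    null_mix = c(0, 0, 1, 0), seed = 31)
  x <- rnorm(n)
  meth <- sim_methylation(cfg, x)
  y <- sim_outcome(cfg, x, meth$beta, meth$truth)
  sc <- scan_mediators(x, meth$beta, y)
  ks <- suppressWarnings(stats::ks.test(sc$p_alpha, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("outcome decomposes into direct plus mediated effects", {
  n <- 10000
  # no mediation anywhere, no direct effect: total effect centered on 0
  cfg0 <- sim_config(n_participants = n, n_mediators = 20,
                     null_mix = c(1, 0, 0, 0), direct_effect = 0,
                     seed = 41)
  x <- rnorm(n)
  me0 <- sim_methylation(cfg0, x)
  y0 <- sim_outcome(cfg0, x, me0$beta, me0$truth)
  f0 <- summary(lm(y0 ~ x))$coefficients["x", ]
  expect_lt(abs(f0["Estimate"]), 3 * f0["Std. Error"])

  # single true mediator: total = direct + alpha * beta
  cfg1 <- sim_config(n_participants = n, n_mediators = 1,
                     null_mix = c(0, 0, 0, 1), alpha_effect = 0.05,
                     beta_effect = 4, direct_effect = 0.3, seed = 42)
  me1 <- sim_methylation(cfg1, x)
  y1 <- sim_outcome(cfg1, x, me1$beta, me1$truth)
  f1 <- summary(lm(y1 ~ x))$coefficients["x", ]
  expect_lt(abs(f1["Estimate"] - 0.5), 3 * f1["Std. Error"])
})

test_that("the noiseless limit reproduces the structural model", {
  n <- 300
  cfg <- sim_config(n_participants = n, n_mediators = 10,
                    noise_sd_outcome = 1e-8, seed = 51)
  x <- rnorm(n)
  meth <- sim_methylation(cfg, x)
  y <- sim_outcome(cfg, x, meth$beta, meth$truth)
  fitted <- cfg$direct_effect * x +
    as.numeric(meth$beta %*% meth$truth$true_beta)
  expect_lt(sd(y - fitted), 1e-6)
})

test_that("written study round-trips through TSV", {
  cfg <- sim_config(n_participants = 20, n_mediators = 15, seed = 6)
  study <- sim_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("phenotype.tsv", "stress_items.tsv", "methylation.tsv",
      "cells_batch.tsv", "truth.tsv", "annotation.tsv", "outcome.tsv",
      "config.tsv")))))
  beta_in <- read_tsv(file.path(dir, "methylation.tsv"))
  expect_equal(as.matrix(beta_in[, -1]),
               study$methylation$beta, ignore_attr = TRUE)
})
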