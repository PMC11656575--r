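# Mediation scan: vectorized OLS, null-proportion estimation, mixture
# correction, BH FDR, proportion mediated.

test_that("vectorized scan matches per-CpG lm fits exactly", {
  set.seed(30)
  n <- 150
  x <- rnorm(n)
  C <- data.frame(age = rnorm(n, 70, 9),
                  sex = factor(sample(c("f", "m"), n, TRUE)))
  M <- matrix(0.5 + 0.03 * x + rnorm(n * 50, sd = 0.05), n, 50,
              dimnames = list(NULL, sprintf("cg%02d", 1:50)))
  y <- 0.3 * x + M %*% rnorm(50, sd = 0.5) + rnorm(n)
  sc <- scan_mediators(x, M, y, C)
  for (j in c(1, 17, 50)) {
    fa <- summary(lm(M[, j] ~ x + C$age + C$sex))$coefficients["x", ]
    fb <- summary(lm(y ~ x + M[, j] + C$age + C$sex))$coefficients["M[, j]", ]
    expect_equal(sc$alpha[j], unname(fa["Estimate"]), tolerance = 1e-10)
    expect_equal(sc$se_alpha[j], unname(fa["Std. Error"]), tolerance = 1e-10)
    expect_equal(sc$p_alpha[j], unname(fa["Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(sc$beta[j], unname(fb["Estimate"]), tolerance = 1e-10)
    expect_equal(sc$se_beta[j], unname(fb["Std. Error"]), tolerance = 1e-10)
    expect_equal(sc$p_beta[j], unname(fb["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("null CpGs give uniform p-values on both paths", {
  set.seed(31)
  n <- 200
  x <- rnorm(n)
  M <- matrix(0.5 + rnorm(n * 3000, sd = 0.05), n, 3000)
  y <- 0.4 * x + rnorm(n)
  sc <- scan_mediators(x, M, y)
  expect_gt(suppressWarnings(ks.test(sc$p_alpha, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(sc$p_beta, "punif"))$p.value, 0.01)
})

test_that("a noiseless exposure-proportional mediator is flagged degenerate", {
  set.seed(32)
  n <- 80
  x <- rnorm(n)
  M <- cbind(exact = 0.1 * x, noisy = 0.1 * x + rnorm(n, sd = 0.05))
  y <- x + rnorm(n)
  expect_message(sc <- scan_mediators(x, M, y), "degenerate")
  expect_true(sc$degenerate[1])
  expect_false(sc$degenerate[2])
  expect_equal(sc$alpha[1], 0.1, tolerance = 1e-12)
  expect_equal(sc$p_alpha[1], 0)
  expect_true(is.na(sc$beta[1]))
})

test_that("constant mediator columns are skipped with a log message", {
  set.seed(33)
  n <- 60
  M <- cbind(const = rep(0.5, n), ok = runif(n))
  expect_message(sc <- scan_mediators(rnorm(n), M, rnorm(n)), "skipped")
  expect_true(sc$degenerate[1])
  expect_false(sc$degenerate[2])
})

test_that("null proportions are recovered from p-value mixtures", {
  set.seed(34)
  # complete null: pi00 -> 1
  pr <- estimate_null_proportions(runif(10000), runif(10000))
  expect_equal(pr$pi00, 1, tolerance = 0.05)
  # half the alpha p-values near zero, beta uniform: pi10 ~ 0.5, pi00 ~ 0.5
  p_a <- c(rep(1e-8, 5000), runif(5000))
  p_b <- runif(10000)
  pr2 <- estimate_null_proportions(p_a, p_b)
  expect_equal(pr2$pi10, 0.5, tolerance = 0.05)
  expect_equal(pr2$pi00, 0.5, tolerance = 0.05)
  # invariant to mediator order
  perm <- sample(10000)
  pr3 <- estimate_null_proportions(p_a[perm], p_b[perm])
  expect_identical(unclass(pr2), unclass(pr3))
  expect_error(estimate_null_proportions(runif(50), runif(50)),
               class = "medewas_insufficient_data_error")
})

test_that("the mixture correction evaluates the composite-null CDF", {
  props <- list(pi00 = 1, pi10 = 0, pi01 = 0)
  expect_equal(corrected_maxp(0.1, props), 0.01, tolerance = 1e-15)
  props01 <- list(pi00 = 0, pi10 = 0, pi01 = 1)
  expect_equal(corrected_maxp(0.1, props01), 0.1, tolerance = 1e-15)
  mix <- list(pi00 = 0.5, pi10 = 0.25, pi01 = 0.25)
  expect_equal(corrected_maxp(0.1, mix), 0.055, tolerance = 1e-15)
  # monotone in t, never above the naive p-value, and in (0, 1]
  t <- sort(runif(100))
  pc <- corrected_maxp(t, mix)
  expect_true(all(diff(pc) >= 0))
  expect_true(all(pc <= t + 1e-15))
  expect_true(all(pc > 0 & pc <= 1))
  expect_error(corrected_maxp(0.5, list(pi00 = 0, pi10 = 0, pi01 = 0)),
               class = "medewas_degenerate_error")
  expect_error(corrected_maxp(1.5, mix), class = "medewas_contract_error")
})

test_that("BH q-values match an independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.42), 0.42)
  set.seed(35)
  p <- runif(500)^2
  q <- bh_fdr(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  # monotone after sorting
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "medewas_contract_error")
})

test_that("proportion mediated is the alpha-beta product over the total", {
  expect_equal(proportion_mediated(0.5, 0.4, 1), 0.2)
  expect_equal(proportion_mediated(0, 0.9, 2), 0)
  expect_error(proportion_mediated(0.5, 0.4, 0),
               class = "medewas_undefined_proportion_error")
})

test_that("scan results are invariant to covariate rescaling and CpG order", {
  set.seed(36)
  n <- 120
  x <- rnorm(n)
  C <- data.frame(a = rnorm(n, 50, 5), b = runif(n))
  M <- matrix(0.5 + 0.02 * x + rnorm(n * 30, sd = 0.05), n, 30,
              dimnames = list(NULL, sprintf("cg%02d", 1:30)))
  y <- x + M %*% rnorm(30) + rnorm(n)
  base <- scan_mediators(x, M, y, C)
  resc <- scan_mediators(x, M, y,
                         data.frame(a = 10 * C$a - 3, b = C$b / 7))
  expect_equal(base$alpha, resc$alpha, tolerance = 1e-9)
  expect_equal(base$p_beta, resc$p_beta, tolerance = 1e-9)
  perm <- sample(30)
  shuffled <- scan_mediators(x, M[, perm], y, C)
  expect_equal(shuffled$alpha, base$alpha[perm], tolerance = 1e-12)
  expect_equal(shuffled$mediator, base$mediator[perm])
})

test_that("mediation_scan assembles maxp, corrected p, q, and proportions", {
  set.seed(37)
  cfg <- sim_config(n_participants = 250, n_mediators = 600,
                    null_mix = c(0.9, 0.03, 0.03, 0.04), seed = 14)
  x <- rnorm(250)
  meth <- sim_methylation(cfg, x)
  y <- sim_outcome(cfg, x, meth$beta, meth$truth)
  M <- preprocess_methylation(meth$beta, meth$cells, meth$plate,
                              meth$position_row, meth$position_col)
  ms <- mediation_scan(x, M, y)
  r <- ms$results
  expect_equal(r$maxp, pmax(r$p_alpha, r$p_beta))
  expect_equal(r$p_corrected, corrected_maxp(r$maxp, ms$null_proportions))
  expect_equal(r$q, bh_fdr(r$p_corrected))
  expect_equal(r$mediation_effect, r$alpha * r$beta)
  expect_equal(r$prop_mediated,
               r$mediation_effect / ms$total_effect)
  # q is non-decreasing in maxp (ties broken by stable order)
  o <- order(r$maxp)
  expect_true(all(diff(r$p_corrected[o]) >= -1e-15))
})
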