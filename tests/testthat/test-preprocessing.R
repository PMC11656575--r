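# Preprocessing: imputation, winsorization vs outlier removal, nuisance
# residualization, medication adjustment, transforms.

test_that("mean imputation fills gaps with the observed CpG mean", {
  M <- cbind(a = c(0.2, NA, 0.4), b = c(0.1, 0.2, 0.3))
  out <- impute_mean(M)
  expect_equal(unname(out[2, "a"]), 0.3)
  expect_equal(out[, "b"], M[, "b"])          # untouched where observed
  expect_equal(colMeans(out)["a"], c(a = 0.3))  # column mean preserved
  expect_identical(impute_mean(out), out)       # idempotent / identity
  expect_error(impute_mean(cbind(c(NA, NA), c(1, 2))),
               class = "medewas_unprocessable_error")
})

test_that("winsorization clamps to type-7 3xIQR fences", {
  x <- c(seq(0.4, 0.6, length.out = 99), 0.99)
  q1 <- q7(x, 0.25); q3 <- q7(x, 0.75)
  upper <- q3 + 3 * (q3 - q1)
  w <- winsorize_iqr(x)
  expect_equal(max(w), upper)
  expect_equal(sum(w != x), 1)                 # only the outlier moved
  expect_identical(order(w), order(x))         # order statistics preserved
  # already-within-fences vector is untouched
  y <- seq(1, 2, length.out = 20)
  expect_equal(as.numeric(winsorize_iqr(y)), y)
  # zero IQR collapses everything to the constant middle
  z <- c(1, rep(2, 8), 9)
  expect_true(all(winsorize_iqr(z) == 2))
  expect_error(winsorize_iqr(c(1, 2, 3)),
               class = "medewas_degenerate_error")
  # matrix version agrees with the vector version column-wise
  M <- cbind(x, rev(x))
  W <- winsorize_matrix(M)
  expect_equal(W[, 1], as.numeric(winsorize_iqr(x)))
})

test_that("outcome outliers are removed, not clamped", {
  x <- c(seq(10, 20, length.out = 50), 99)
  out <- remove_outliers_iqr(x)
  expect_equal(sum(out$excluded), 1)
  expect_true(is.na(out$values[51]))
  # no outliers: zero exclusions
  expect_equal(sum(remove_outliers_iqr(seq(1, 2, length.out = 30))$excluded),
               0)
  # affine equivariance of the fences: same exclusion count
  out2 <- remove_outliers_iqr(-5 + 3 * x)
  expect_identical(out2$excluded, out$excluded)
})

test_that("residualization removes nuisance signal exactly", {
  set.seed(10)
  n <- 120
  cells <- matrix(rgamma(n * 4, 2), n, 4); cells <- cells / rowSums(cells)
  plate <- factor(rep(c("p1", "p2"), length.out = n))
  gamma <- c(0.3, -0.2, 0.1)
  M <- cbind(
    cpg1 = 0.5 + cells[, 1:3] %*% gamma + rnorm(n, sd = 0.02),
    cpg2 = 0.4 + 0.1 * (plate == "p2") + rnorm(n, sd = 0.02)
  )
  R <- residualize_methylation(M, cells, plate = plate)
  # residuals orthogonal to cell proportions
  for (k in 1:3) {
    expect_lt(abs(cor(R[, 1], cells[, k])), 1e-10)
  }
  # plate mean shift absorbed: equal plate means
  pm <- tapply(R[, 2], plate, mean)
  expect_equal(unname(diff(pm)), 0, tolerance = 1e-12)
  # re-centered at the CpG means
  expect_equal(colMeans(R), colMeans(M), tolerance = 1e-12)
  # regressing residuals on the same design again gives ~zero coefficients
  again <- lm(R[, 1] ~ cells[, 1:3] + plate)
  expect_lt(max(abs(coef(again)[-1])), 1e-8)
  # idempotent: residualizing twice changes nothing
  expect_equal(residualize_methylation(R, cells, plate = plate), R,
               tolerance = 1e-12)
})

test_that("constant cell proportions are absorbed by the intercept", {
  n <- 30
  M <- cbind(cpg = seq(0.3, 0.6, length.out = n))
  cells <- matrix(rep(c(0.5, 0.3, 0.2), each = n), n, 3)
  R <- residualize_methylation(M, cells)
  expect_equal(R, M, tolerance = 1e-12)
})

test_that("rank-deficient nuisance designs are rejected", {
  set.seed(11)
  n <- 30
  M <- cbind(cpg = runif(n))
  cells <- matrix(runif(n * 3), n, 3)
  cells <- cells / rowSums(cells)
  # duplicated factor: plate identical to position row
  f <- factor(rep(c("a", "b"), length.out = n))
  expect_error(residualize_methylation(M, cells, plate = f,
                                       position_row = f),
               class = "medewas_collinearity_error")
})

test_that("medication adjustments follow the pharmacological constants", {
  expect_equal(adjust_medication("SBP", 120, antihypertensive = TRUE)$adjusted,
               135)
  expect_equal(adjust_medication("SBP", 120, antihypertensive = FALSE)$adjusted,
               120)
  expect_equal(adjust_medication("DBP", 80, antihypertensive = TRUE)$adjusted,
               90)
  expect_equal(adjust_medication("LDL-C", 70, statin = TRUE)$adjusted, 100)
  expect_equal(adjust_medication("TC", 160, statin = TRUE)$adjusted, 200)
  # HDL-C and TG are never medication-adjusted
  expect_equal(adjust_medication("HDL-C", 55, statin = TRUE)$adjusted, 55)
  expect_equal(adjust_medication("TG", 140, statin = TRUE)$adjusted, 140)
  # glucose under diabetes medication is excluded, not adjusted
  g <- adjust_medication("glucose", c(100, 110), diabetes_med = c(TRUE, FALSE))
  expect_true(g$excluded[1] && !g$excluded[2])
  expect_true(is.na(g$adjusted[1]))
  expect_equal(g$reason[1], "diabetes_medication")
  expect_equal(adjust_medication("BMI", 30)$adjusted, 30)
  expect_error(adjust_medication("pulse", 70), class = "medewas_schema_error")
})

test_that("log transform applies to glucose and CRP only", {
  expect_equal(transform_outcome("CRP", 1), 0)
  expect_equal(transform_outcome("glucose", exp(2)), 2)
  expect_equal(transform_outcome("BMI", 30), 30)
  expect_error(transform_outcome("CRP", c(1, -0.2)),
               class = "medewas_domain_error")
})

test_that("outcome pipeline applies outlier, medication, transform in order", {
  set.seed(12)
  glucose <- c(rnorm(60, 100, 5), 600)   # one gross outlier
  diab <- c(rep(FALSE, 30), rep(TRUE, 31))
  res <- preprocess_outcome("glucose", glucose, diabetes_med = diab)
  expect_equal(sum(res$reason == "outlier_3iqr", na.rm = TRUE), 1)
  expect_true(all(res$excluded[31:61]))
  kept <- !res$excluded
  expect_equal(res$value[kept], log(glucose[kept]))
  expect_true(all(res$transform == "log"))
  expect_true(all(preprocess_outcome("BMI", rnorm(30, 30))$transform ==
                    "identity"))
})
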