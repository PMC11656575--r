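# Total-effect models and cohort comparison.
#
# Model 1: outcome ~ stress + age + sex + education + measurement year +
# ancestry PCs (+ fasting for the blood-draw outcomes).  Model 2 adds
# smoking-status categories.  The variance in the outcome attributable to
# stress is the drop in R-squared when stress is removed, divided by the
# full-model R-squared.

#' Fit the total effect of stress on an outcome
#'
#' Ordinary least squares of the outcome on the standardized stress
#' exposure plus covariates, on complete cases.  Factors in the covariate
#' table are expanded to treatment-coded dummies (first level reference).
#'
#' @param y numeric outcome vector.
#' @param x numeric exposure vector (SD units).
#' @param covariates optional data frame of covariates (numeric columns
#'   and/or factors).
#' @param smoking optional smoking-status factor; supplying it with
#'   `model = 2` adds it to the design.
#' @param model 1 or 2.
#' @return one-row data frame: `estimate` (outcome units per SD stress),
#'   `se`, `statistic`, `p`, `r2_full`, `r2_reduced`, `var_explained`
#'   (fraction of the full-model R-squared attributable to stress), `n`,
#'   `model`.  The underlying full and reduced [stats::lm] fits are
#'   attached as attributes `fit_full` / `fit_reduced`.
#' @export
fit_total_effect <- function(y, x, covariates = NULL, smoking = NULL,
                             model = 1) {
  .assert(model %in% c(1, 2), "`model` must be 1 or 2",
          "medewas_config_error")
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    .assert(nrow(covariates) == length(y),
            "`covariates` rows must match `y`", "medewas_dimension_error")
    dat <- cbind(dat, covariates)
  }
  if (model == 2) {
    .assert(!is.null(smoking), "model 2 requires `smoking`",
            "medewas_config_error")
    dat$.smoking <- as.factor(smoking)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- setdiff(names(dat), ".y")
  .assert(nrow(dat) > length(rhs) + 2,
          "too few complete cases for the requested design",
          "medewas_insufficient_data_error")
  fml <- stats::reformulate(sprintf("`%s`", rhs), response = ".y")
  fit_full <- stats::lm(fml, data = dat)
  .assert(!any(is.na(stats::coef(fit_full))),
          "collinear design in total-effect model",
          "medewas_collinearity_error")
  rhs_red <- setdiff(rhs, ".x")
  fml_red <- if (length(rhs_red) == 0) stats::as.formula(".y ~ 1") else
    stats::reformulate(sprintf("`%s`", rhs_red), response = ".y")
  fit_reduced <- stats::lm(fml_red, data = dat)
  sm <- summary(fit_full)
  co <- sm$coefficients[".x", ]
  r2_full <- sm$r.squared
  r2_reduced <- summary(fit_reduced)$r.squared
  out <- data.frame(
    estimate = co[["Estimate"]], se = co[["Std. Error"]],
    statistic = co[["t value"]], p = co[["Pr(>|t|)"]],
    r2_full = r2_full, r2_reduced = r2_reduced,
    var_explained = if (r2_full > 0) (r2_full - r2_reduced) / r2_full else
      NA_real_,
    n = nrow(dat), model = model
  )
  attr(out, "fit_full") <- fit_full
  attr(out, "fit_reduced") <- fit_reduced
  out
}

#' Fraction of outcome variance explained by the exposure
#'
#' `(R2_full - R2_reduced) / R2_full` for a nested pair of linear models
#' fit on the same rows.
#'
#' @param fit_full,fit_reduced [stats::lm] fits; `fit_reduced` must use a
#'   subset of the full model's terms and identical rows.
#' @return fraction in `[0, 1]`.
#' @export
variance_explained <- function(fit_full, fit_reduced) {
  .assert(inherits(fit_full, "lm") && inherits(fit_reduced, "lm"),
          "both arguments must be lm fits", "medewas_contract_error")
  .assert(stats::nobs(fit_full) == stats::nobs(fit_reduced),
          "fits use different numbers of rows", "medewas_contract_error")
  t_full <- attr(stats::terms(fit_full), "term.labels")
  t_red <- attr(stats::terms(fit_reduced), "term.labels")
  .assert(all(t_red %in% t_full),
          "`fit_reduced` is not nested in `fit_full`",
          "medewas_contract_error")
  r2_full <- summary(fit_full)$r.squared
  r2_red <- summary(fit_reduced)$r.squared
  .assert(r2_full >= r2_red,
          "full-model R-squared below reduced model: fits are inconsistent",
          "medewas_contract_error")
  (r2_full - r2_red) / r2_full
}

#' @keywords internal
#' @noRd
.cramers_v <- function(tab) {
  n <- sum(tab)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic
  )
  as.numeric(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

#' @keywords internal
#' @noRd
.cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Compare included and excluded cohorts
#'
#' For each shared variable: chi-squared test plus Cramer's V for
#' categorical variables; Welch two-sample t-test plus Cohen's d (pooled
#' SD) for continuous ones.
#'
#' @param included,excluded data frames with a shared variable schema.
#' @param variables variables to compare; defaults to the shared columns.
#' @return data frame: `variable`, `type`, `statistic`, `p`,
#'   `effect_size` (Cramer's V or Cohen's d).
#' @export
compare_cohorts <- function(included, excluded,
                            variables = intersect(names(included),
                                                  names(excluded))) {
  .assert(nrow(included) > 0 && nrow(excluded) > 0,
          "both cohorts must be non-empty",
          "medewas_insufficient_data_error")
  rows <- lapply(variables, function(v) {
    a <- included[[v]]; b <- excluded[[v]]
    if (is.numeric(a) && is.numeric(b)) {
      tt <- stats::t.test(a, b)
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 effect_size = .cohens_d(a, b), stringsAsFactors = FALSE)
    } else {
      g <- factor(c(rep("included", length(a)), rep("excluded", length(b))))
      val <- factor(c(as.character(a), as.character(b)))
      tab <- table(g, val)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 effect_size = .cramers_v(tab), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
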