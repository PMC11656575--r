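# Epigenome-wide mediation scan.
#
# For each CpG j the two working models are
#   (1)  M_j = a0 + alpha_j X + a_C' C + e_Mj
#   (2)  Y   = b0 + betaX_j X + beta_j M_j + b_C' C + e_Yj
# The mediation null H0: alpha_j * beta_j = 0 is composite -- it holds when
# either path coefficient is zero -- so the max of the two component
# p-values is not uniform under the null.  The scan corrects the MaxP
# statistic against a mixture reference distribution whose weights are the
# estimated proportions of the three null configurations.

#' Per-CpG exposure-mediator and mediator-outcome regressions
#'
#' Vectorized OLS over all mediator columns.  The alpha path regresses each
#' `M_j` on the exposure and covariates; the beta path regresses `Y` on the
#' exposure, `M_j`, and covariates, computed by Frisch-Waugh-Lovell
#' residualization so that one QR decomposition serves every CpG.  Results
#' are identical to looping `lm()` over CpGs.
#'
#' Constant (or collinear-with-design) mediator columns cannot support the
#' beta regression; they are flagged `degenerate`, their statistics are
#' `NA`, and a message lists them.
#'
#' @param x numeric exposure vector.
#' @param M numeric mediator matrix, participants x CpGs.
#' @param y numeric outcome vector.
#' @param covariates optional data frame or matrix of covariates; factors
#'   are expanded to dummies.
#' @return data frame, one row per CpG: `mediator`, `alpha`, `se_alpha`,
#'   `p_alpha`, `beta`, `se_beta`, `p_beta`, `degenerate`.
#' @export
scan_mediators <- function(x, M, y, covariates = NULL) {
  M <- as.matrix(M)
  y <- as.numeric(y)
  n <- length(x)
  .assert(nrow(M) == n && length(y) == n,
          "`x`, `M` rows, and `y` must conform", "medewas_dimension_error")
  .assert(!anyNA(x) && !anyNA(y) && !anyNA(M),
          "inputs must be complete (preprocess first)",
          "medewas_unprocessable_error")
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    .assert(nrow(covariates) == n, "`covariates` rows must match `x`",
            "medewas_dimension_error")
    C <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  D <- cbind(`(Intercept)` = 1, C, x = x)
  p <- ncol(D)
  .assert(n > p + 1, "more design columns than observations",
          "medewas_insufficient_data_error")
  qr_d <- qr(D)
  .assert(qr_d$rank == p, "collinear exposure/covariate design",
          "medewas_collinearity_error")

  # alpha path: M_j ~ D, coefficient on x
  coefs <- qr.coef(qr_d, M)
  alpha <- coefs["x", ]
  res_m <- qr.resid(qr_d, M)
  rss_m <- colSums(res_m^2)
  xtxinv_xx <- chol2inv(qr.R(qr_d))[p, p]
  df_a <- n - p
  sigma2_a <- rss_m / df_a
  se_alpha <- sqrt(sigma2_a * xtxinv_xx)
  t_alpha <- alpha / se_alpha
  p_alpha <- 2 * stats::pt(-abs(t_alpha), df = df_a)

  # beta path by FWL: residualize y and M_j on [1, C, x], then simple OLS
  res_y <- qr.resid(qr_d, y)
  ssm <- rss_m
  degenerate <- ssm <= n * .Machine$double.eps^0.75 *
    pmax(colSums(M^2) / n, 1)
  ssm_safe <- ifelse(degenerate, NA_real_, ssm)
  beta <- colSums(res_m * res_y) / ssm_safe
  df_b <- n - p - 1
  rss_b <- sum(res_y^2) - beta^2 * ssm_safe
  rss_b <- pmax(rss_b, 0)
  se_beta <- sqrt(rss_b / df_b / ssm_safe)
  t_beta <- beta / se_beta
  p_beta <- 2 * stats::pt(-abs(t_beta), df = df_b)

  if (any(degenerate)) {
    message("scan_mediators: skipped ", sum(degenerate),
            " degenerate mediator column(s): ",
            paste(utils::head(colnames(M)[degenerate], 5), collapse = ", "))
  }
  ids <- colnames(M)
  if (is.null(ids)) ids <- sprintf("M%d", seq_len(ncol(M)))
  data.frame(mediator = ids, alpha = alpha, se_alpha = se_alpha,
             p_alpha = p_alpha, beta = beta, se_beta = se_beta,
             p_beta = p_beta, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate the composite-null component proportions
#'
#' Storey-type tail estimators applied separately to the alpha-path and
#' beta-path p-values: \eqn{\hat\pi_{\alpha 0} = \#\{p_\alpha > \lambda\} /
#' (J (1 - \lambda))} (truncated to 1), likewise for beta.  The four joint
#' proportions are combined under cross-independence of the two null
#' memberships: `pi00 = pi_a0 * pi_b0`, `pi10 = (1 - pi_a0) * pi_b0`,
#' `pi01 = pi_a0 * (1 - pi_b0)`, `pi11` the remainder.
#'
#' @param p_alpha,p_beta p-value vectors of equal length `J >= 100`.
#' @param lambda tail threshold in (0, 1), default 0.5.
#' @return object of class `null_proportions`: list with `pi00`, `pi10`,
#'   `pi01`, `pi11`, the marginal `pi_alpha0`, `pi_beta0`, and `lambda`.
#' @export
estimate_null_proportions <- function(p_alpha, p_beta, lambda = 0.5) {
  keep <- !is.na(p_alpha) & !is.na(p_beta)
  p_alpha <- p_alpha[keep]; p_beta <- p_beta[keep]
  J <- length(p_alpha)
  .assert(length(p_beta) == J, "p-value vectors must have equal length",
          "medewas_dimension_error")
  .assert(J >= 100, "need at least 100 mediators to estimate proportions",
          "medewas_insufficient_data_error")
  .assert(lambda > 0 && lambda < 1, "`lambda` must lie in (0, 1)",
          "medewas_config_error")
  pi_a0 <- min(1, mean(p_alpha > lambda) / (1 - lambda))
  pi_b0 <- min(1, mean(p_beta > lambda) / (1 - lambda))
  clamp <- function(v) min(1, max(0, v))
  structure(list(
    pi00 = clamp(pi_a0 * pi_b0),
    pi10 = clamp((1 - pi_a0) * pi_b0),
    pi01 = clamp(pi_a0 * (1 - pi_b0)),
    pi11 = clamp((1 - pi_a0) * (1 - pi_b0)),
    pi_alpha0 = pi_a0, pi_beta0 = pi_b0, lambda = lambda
  ), class = "null_proportions")
}

#' Correct MaxP p-values against the composite-null mixture
#'
#' Under the three null configurations the MaxP statistic
#' `t = max(p_alpha, p_beta)` has CDF `t` (single null, the non-null path
#' detected) or `t^2` (double null).  The corrected p-value is the mixture
#' CDF normalized over the null mass:
#' \deqn{p_{corr}(t) = \frac{\pi_{01} t + \pi_{10} t + \pi_{00} t^2}
#'   {\pi_{01} + \pi_{10} + \pi_{00}}}
#' clipped into `(0, 1]`.  It is non-decreasing in `t` and never exceeds
#' the naive uniform-reference p-value `t`.
#'
#' @param maxp numeric vector of MaxP statistics in `[0, 1]`.
#' @param props a `null_proportions` object (or list with `pi00`, `pi10`,
#'   `pi01`).
#' @return corrected p-value vector.
#' @export
corrected_maxp <- function(maxp, props) {
  .assert(all(is.na(maxp) | (maxp >= 0 & maxp <= 1)),
          "`maxp` values must lie in [0, 1]", "medewas_contract_error")
  mass <- props$pi00 + props$pi10 + props$pi01
  .assert(is.finite(mass) && mass > 0,
          "zero null mass: mixture correction undefined",
          "medewas_degenerate_error")
  p <- (props$pi01 * maxp + props$pi10 * maxp + props$pi00 * maxp^2) / mass
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (monotone cumulative minima), delegated to
#' [stats::p.adjust].
#'
#' @param p p-value vector in `[0, 1]`.
#' @return q-value vector of the same length.
#' @export
bh_fdr <- function(p) {
  .assert(all(is.na(p) | (p >= 0 & p <= 1)),
          "p-values must lie in [0, 1]", "medewas_contract_error")
  stats::p.adjust(p, method = "BH")
}

#' Proportion of the total effect mediated
#'
#' `alpha * beta / total_effect`.  May fall outside `[0, 1]` under
#' inconsistent mediation; values are reported as-is.
#'
#' @param alpha,beta path coefficient estimates (vectorized).
#' @param total_effect total effect of the exposure on the outcome
#'   (nonzero scalar).
#' @return numeric vector of mediated proportions.
#' @export
proportion_mediated <- function(alpha, beta, total_effect) {
  .assert(length(total_effect) == 1 && is.finite(total_effect) &&
            total_effect != 0,
          "`total_effect` must be a nonzero scalar",
          "medewas_undefined_proportion_error")
  alpha * beta / total_effect
}

#' Run the full epigenome-wide mediation scan
#'
#' [scan_mediators()] plus the composite-null machinery: MaxP statistics,
#' mixture-corrected p-values, BH q-values, per-CpG mediation effects
#' `alpha * beta`, and (when a total effect is available) the proportion
#' mediated.  Rows keep the input CpG order; ties in MaxP are therefore
#' broken by stable mediator order in any sorted report.
#'
#' @inheritParams scan_mediators
#' @param total_effect total effect of `x` on `y`; if `NULL` it is
#'   estimated by OLS of `y` on `x` and the covariates on the same rows.
#' @param lambda Storey tail threshold for null-proportion estimation.
#' @param q_threshold FDR threshold defining `significant`, default 0.05.
#' @return object of class `mediation_scan`: list with `results` (per-CpG
#'   data frame adding `maxp`, `p_corrected`, `q`, `mediation_effect`,
#'   `prop_mediated`, `significant`), `null_proportions`, `total_effect`.
#' @export
mediation_scan <- function(x, M, y, covariates = NULL, total_effect = NULL,
                           lambda = 0.5, q_threshold = 0.05) {
  res <- scan_mediators(x, M, y, covariates)
  if (is.null(total_effect)) {
    total_effect <- fit_total_effect(y, x, covariates)$estimate
  }
  props <- estimate_null_proportions(res$p_alpha, res$p_beta,
                                     lambda = lambda)
  res$maxp <- pmax(res$p_alpha, res$p_beta)
  res$p_corrected <- corrected_maxp(res$maxp, props)
  res$q <- bh_fdr(res$p_corrected)
  res$mediation_effect <- res$alpha * res$beta
  res$prop_mediated <- if (total_effect != 0)
    proportion_mediated(res$alpha, res$beta, total_effect) else NA_real_
  res$significant <- !is.na(res$q) & res$q < q_threshold & !res$degenerate
  structure(list(results = res, null_proportions = props,
                 total_effect = total_effect,
                 q_threshold = q_threshold),
            class = "mediation_scan")
}
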