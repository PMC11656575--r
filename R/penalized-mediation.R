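# De-biased LASSO multivariable mediation.
#
# The scan's per-CpG beta coefficients ignore the other mediating CpGs.
# Here the outcome is regressed on all selected CpGs jointly with a LASSO
# penalty on the CpG columns only (exposure and covariates unpenalized),
# and each CpG coefficient is de-biased with the node-wise-regression
# (desparsified LASSO) correction, restoring asymptotically normal
# per-coefficient inference.  Joint significance then reuses the same
# mixture-null MaxP machinery as the scan, pairing each CpG's
# exposure-mediator p-value with its adjusted mediator-outcome p-value.

#' De-biased LASSO estimates of mediator-outcome coefficients
#'
#' Fits `Y ~ X + M_sel + C` with an L1 penalty on the mediator columns
#' only, then de-biases each mediator coefficient:
#' \deqn{\tilde b_j = \hat b_j + z_j'(y - D\hat b) / z_j' D_j}
#' where `z_j` is the residual of the node-wise regression of mediator
#' column `D_j` on all other design columns.  At zero penalty the
#' correction vanishes against the OLS residual and the estimates equal
#' multivariable OLS.  Standard errors use
#' \eqn{\hat\sigma \|z_j\|_2 / |z_j' D_j|} with the residual SD from the
#' penalized fit.
#'
#' This targets the intended regime of tens of pre-screened mediators with
#' `p` well below `n`; designs with `p >= n` are rejected.
#'
#' @param y outcome vector.
#' @param x exposure vector.
#' @param M_sel matrix of selected CpG mediators (participants x CpGs).
#' @param covariates optional covariate data frame or matrix (unpenalized).
#' @param lambda penalty: `"cv.1se"` (default; 10-fold cross-validation,
#'   1-SE rule), `"cv.min"`, or a non-negative number.  `0` gives OLS.
#' @param nodewise_lambda penalty rule for the node-wise regressions, same
#'   choices; default `"cv.min"`.
#' @param nfolds CV folds, default 10.
#' @param seed integer seed fixing the CV fold assignment.
#' @return data frame, one row per mediator: `mediator`, `beta`
#'   (de-biased), `se`, `p`, `beta_lasso` (penalized estimate), plus
#'   attributes `lambda` and `sigma`.
#' @export
debiased_lasso_outcome <- function(y, x, M_sel, covariates = NULL,
                                   lambda = "cv.1se",
                                   nodewise_lambda = "cv.min",
                                   nfolds = 10L, seed = NULL) {
  M_sel <- as.matrix(M_sel)
  n <- length(y)
  .assert(length(x) == n && nrow(M_sel) == n,
          "`y`, `x`, `M_sel` must conform", "medewas_dimension_error")
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    C <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  p_med <- ncol(M_sel)
  ids <- colnames(M_sel)
  if (is.null(ids)) ids <- sprintf("M%d", seq_len(p_med))
  D <- cbind(x = x, M_sel, C)
  p_tot <- ncol(D)
  .assert(p_tot + 1 < n,
          paste0("p >= n regime unsupported: screen mediators first ",
                 "(got ", p_tot, " design columns for ", n, " rows)"),
          "medewas_unsupported_regime_error")
  .assert(qr(D)$rank == p_tot,
          "collinear design: duplicated or linearly dependent mediators",
          "medewas_collinearity_error")
  Dc <- scale(D, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  med_idx <- 1L + seq_len(p_med)
  pf <- rep(0, p_tot); pf[med_idx] <- 1

  if (!is.null(seed)) set.seed(.child_seed(seed, 1L))
  foldid <- sample(rep_len(seq_len(nfolds), n))
  pick_lambda <- function(X, yy, pfac, rule) {
    if (is.numeric(rule)) return(rule)
    cv <- glmnet::cv.glmnet(X, yy, penalty.factor = pfac,
                            foldid = foldid, standardize = TRUE,
                            intercept = FALSE)
    if (rule == "cv.min") cv$lambda.min else cv$lambda.1se
  }
  lam <- pick_lambda(Dc, yc, pf, lambda)
  b_hat <- if (lam == 0) {
    stats::lm.fit(Dc, yc)$coefficients
  } else {
    fit <- glmnet::glmnet(Dc, yc, penalty.factor = pf, lambda = lam,
                          standardize = TRUE, intercept = FALSE)
    as.numeric(fit$beta)
  }
  r <- yc - as.numeric(Dc %*% b_hat)
  df_used <- sum(b_hat != 0)
  sigma <- sqrt(sum(r^2) / max(n - df_used - 1, 1))

  beta_deb <- se <- numeric(p_med)
  for (jj in seq_len(p_med)) {
    j <- med_idx[jj]
    lam_j <- pick_lambda(Dc[, -j, drop = FALSE], Dc[, j],
                         rep(1, p_tot - 1), nodewise_lambda)
    g <- if (lam_j == 0) {
      stats::lm.fit(Dc[, -j, drop = FALSE], Dc[, j])$coefficients
    } else {
      nf <- glmnet::glmnet(Dc[, -j, drop = FALSE], Dc[, j],
                           lambda = lam_j, standardize = TRUE,
                           intercept = FALSE)
      as.numeric(nf$beta)
    }
    z_j <- Dc[, j] - as.numeric(Dc[, -j, drop = FALSE] %*% g)
    zd <- sum(z_j * Dc[, j])
    .assert(abs(zd) > 0, "degenerate node-wise residual",
            "medewas_collinearity_error")
    beta_deb[jj] <- b_hat[j] + sum(z_j * r) / zd
    se[jj] <- sigma * sqrt(sum(z_j^2)) / abs(zd)
  }
  out <- data.frame(
    mediator = ids, beta = beta_deb, se = se,
    p = 2 * stats::pnorm(-abs(beta_deb / se)),
    beta_lasso = b_hat[med_idx],
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- lam
  attr(out, "sigma") <- sigma
  out
}

#' Joint significance test with the composite-null mixture
#'
#' Pairs each selected CpG's exposure-mediator p-value with its adjusted
#' mediator-outcome p-value, forms MaxP, corrects against the mixture
#' null CDF, and applies BH FDR.  Null proportions are re-estimated on
#' the selected set when it holds at least `min_reestimate` CpGs;
#' smaller sets must inherit proportions from the genome-wide scan via
#' `props`.
#'
#' @param p_alpha,p_beta_adjusted aligned p-value vectors for the
#'   selected CpGs.
#' @param props optional `null_proportions` (e.g. from the scan).
#' @param lambda Storey threshold used when re-estimating.
#' @param min_reestimate minimum set size for re-estimation, default 100.
#' @return data frame: `maxp`, `p_corrected`, `q` (empty input gives an
#'   empty frame).
#' @export
joint_mixture_test <- function(p_alpha, p_beta_adjusted, props = NULL,
                               lambda = 0.5, min_reestimate = 100L) {
  .assert(length(p_alpha) == length(p_beta_adjusted),
          "p-value vectors must be aligned", "medewas_dimension_error")
  if (length(p_alpha) == 0) {
    return(data.frame(maxp = numeric(0), p_corrected = numeric(0),
                      q = numeric(0)))
  }
  if (is.null(props)) {
    .assert(length(p_alpha) >= min_reestimate,
            paste0("selected set too small to re-estimate null ",
                   "proportions; pass `props` from the scan"),
            "medewas_insufficient_data_error")
    props <- estimate_null_proportions(p_alpha, p_beta_adjusted,
                                       lambda = lambda)
  }
  maxp <- pmax(p_alpha, p_beta_adjusted)
  p_corr <- corrected_maxp(maxp, props)
  data.frame(maxp = maxp, p_corrected = p_corr, q = bh_fdr(p_corr))
}

#' Multivariable mediation over the scan-selected CpGs
#'
#' Runs [debiased_lasso_outcome()] on the selected CpG set, joins the
#' scan's alpha-path statistics, applies [joint_mixture_test()], and
#' reports each CpG's proportion mediated adjusted for its co-mediators
#' (`alpha * beta_debiased / total_effect`).
#'
#' @inheritParams debiased_lasso_outcome
#' @param alpha,p_alpha alpha-path estimates and p-values aligned to the
#'   columns of `M_sel` (from the scan).
#' @param total_effect total effect of `x` on `y`.
#' @param props `null_proportions` inherited from the scan (used when the
#'   selected set is small).
#' @param q_threshold FDR threshold, default 0.05.
#' @return object of class `penalized_mediation`: list with `results`
#'   (per-CpG data frame) and `lambda`.
#' @export
penalized_mediation <- function(x, M_sel, y, covariates = NULL,
                                alpha, p_alpha, total_effect,
                                props = NULL, lambda = "cv.1se",
                                nodewise_lambda = "cv.min",
                                nfolds = 10L, seed = NULL,
                                q_threshold = 0.05) {
  M_sel <- as.matrix(M_sel)
  .assert(length(alpha) == ncol(M_sel) &&
            length(p_alpha) == ncol(M_sel),
          "`alpha`/`p_alpha` must align with `M_sel` columns",
          "medewas_dimension_error")
  deb <- debiased_lasso_outcome(y, x, M_sel, covariates,
                                lambda = lambda,
                                nodewise_lambda = nodewise_lambda,
                                nfolds = nfolds, seed = seed)
  jt <- joint_mixture_test(p_alpha, deb$p, props = props)
  res <- data.frame(
    mediator = deb$mediator, alpha = alpha, p_alpha = p_alpha,
    beta_adjusted = deb$beta, se_beta = deb$se, p_beta_adjusted = deb$p,
    maxp = jt$maxp, p_corrected = jt$p_corrected, q = jt$q,
    prop_mediated_adjusted = proportion_mediated(alpha, deb$beta,
                                                 total_effect),
    stringsAsFactors = FALSE
  )
  res$significant <- !is.na(res$q) & res$q < q_threshold
  structure(list(results = res, lambda = attr(deb, "lambda"),
                 total_effect = total_effect),
            class = "penalized_mediation")
}
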