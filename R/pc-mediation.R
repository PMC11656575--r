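# Principal-component mediation.
#
# The per-CpG scan cannot quantify the joint mediation of correlated CpGs,
# so the significant mediators are reduced to their top principal
# components -- mutually uncorrelated by construction -- and each PC's
# average causal mediation effect (ACME) is estimated by nonparametric
# bootstrap.  Because the PCs are uncorrelated, the summed proportion
# mediated over significant PCs is a lower bound on the overall mediation
# effect of the CpG set.

#' Principal components of the selected mediators
#'
#' Columns are centered and (by default) scaled to unit variance before
#' the singular value decomposition.  Signs follow a deterministic
#' convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param M_sel numeric matrix of the selected CpGs (participants x CpGs).
#' @param k number of components to keep; default 10, or 5 when fewer
#'   than 10 CpGs are supplied, always capped at `min(n - 1, ncol)`.
#' @param scale. scale columns to unit variance (default `TRUE`).
#' @return list with `scores` (n x k), `loadings` (CpGs x k), `var_frac`
#'   (variance fraction of each kept component), `k`.
#' @export
mediator_pcs <- function(M_sel, k = NULL, scale. = TRUE) {
  M_sel <- as.matrix(M_sel)
  n <- nrow(M_sel); p <- ncol(M_sel)
  .assert(p >= 1 && n >= 3, "need at least one CpG and three participants",
          "medewas_dimension_error")
  kmax <- min(n - 1, p)
  if (is.null(k)) k <- if (p < 10) min(5L, kmax) else min(10L, kmax)
  .assert(k >= 1 && k <= kmax,
          sprintf("`k` must lie in [1, %d]", kmax),
          "medewas_dimension_error")
  if (scale.) {
    sds <- apply(M_sel, 2, stats::sd)
    .assert(all(sds > 0),
            "constant CpG column cannot be scaled for PCA",
            "medewas_degenerate_error")
  }
  pc <- stats::prcomp(M_sel, center = TRUE, scale. = scale.)
  var_all <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       var_frac = var_all[seq_len(k)], k = k)
}

#' @keywords internal
#' @noRd
.mediate_point <- function(x, m, y, C = NULL) {
  D_xc <- cbind(1, x, C)
  D_full <- cbind(1, x, m, C)
  a <- stats::lm.fit(D_xc, m)$coefficients[2]
  cf <- stats::lm.fit(D_full, y)$coefficients
  b <- cf[3]; direct <- cf[2]
  total <- stats::lm.fit(D_xc, y)$coefficients[2]
  c(acme = unname(a * b), total = unname(total), direct = unname(direct),
    a = unname(a), b = unname(b))
}

#' Bootstrap mediation analysis of a single mediator (PC score)
#'
#' Point estimates come from the two linear models (mediator on exposure
#' and covariates; outcome on exposure, mediator, and covariates); the
#' ACME is the product of the two path coefficients, and the proportion
#' mediated divides it by the total effect from the exposure-only outcome
#' model on the same rows.  In a linear no-interaction model the product
#' ACME equals the total-minus-direct difference exactly.  Percentile
#' confidence intervals come from resampling participants with
#' replacement; a resample with constant exposure is redrawn and counted.
#'
#' @param x exposure vector.
#' @param m mediator vector (e.g. one PC score).
#' @param y outcome vector.
#' @param covariates optional covariate data frame or matrix.
#' @param n_boot number of bootstrap iterations (>= 500 recommended for
#'   CIs).
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level, default 0.95.
#' @return one-row data frame: `acme`, `acme_lower`, `acme_upper`,
#'   `total_effect`, `direct_effect`, `prop_mediated`, `prop_lower`,
#'   `prop_upper`, `significant` (ACME CI excludes 0), `n_boot`,
#'   `n_redraws`.
#' @export
mediate_single <- function(x, m, y, covariates = NULL, n_boot = 1000L,
                           seed = NULL, conf = 0.95) {
  n <- length(x)
  .assert(length(m) == n && length(y) == n,
          "`x`, `m`, `y` must have equal length", "medewas_dimension_error")
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    C <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  pt <- .mediate_point(x, m, y, C)
  if (!is.null(seed)) set.seed(seed)
  acme_b <- numeric(n_boot); prop_b <- numeric(n_boot)
  n_redraws <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0) break
      n_redraws <- n_redraws + 1L
    }
    bt <- .mediate_point(x[idx], m[idx], y[idx],
                         if (is.null(C)) NULL else C[idx, , drop = FALSE])
    acme_b[i] <- bt[["acme"]]
    prop_b[i] <- if (bt[["total"]] != 0) bt[["acme"]] / bt[["total"]] else
      NA_real_
  }
  alpha2 <- (1 - conf) / 2
  ci <- stats::quantile(acme_b, c(alpha2, 1 - alpha2), names = FALSE)
  ci_p <- stats::quantile(prop_b, c(alpha2, 1 - alpha2), names = FALSE,
                          na.rm = TRUE)
  data.frame(
    acme = pt[["acme"]], acme_lower = ci[1], acme_upper = ci[2],
    total_effect = pt[["total"]], direct_effect = pt[["direct"]],
    prop_mediated = if (pt[["total"]] != 0)
      pt[["acme"]] / pt[["total"]] else NA_real_,
    prop_lower = ci_p[1], prop_upper = ci_p[2],
    significant = ci[1] > 0 | ci[2] < 0,
    n_boot = n_boot, n_redraws = n_redraws
  )
}

#' PC-based cumulative mediation analysis
#'
#' Computes the top principal components of the selected CpGs and runs a
#' bootstrap mediation analysis on each PC score.  The cumulative
#' proportion mediated sums the per-PC proportions over PCs whose ACME CI
#' excludes zero.
#'
#' @inheritParams mediate_single
#' @param M_sel matrix of selected CpG mediators.
#' @param k number of PCs (see [mediator_pcs()]).
#' @param scale. scale CpGs before PCA, default `TRUE`.
#' @return object of class `pc_mediation`: list with `results` (one row
#'   per PC, adding `pc` and `var_frac`), `cumulative_prop` (sum of
#'   `prop_mediated` over significant PCs), `pca` (the [mediator_pcs()]
#'   value).
#' @export
pc_mediation <- function(x, M_sel, y, covariates = NULL, k = NULL,
                         n_boot = 1000L, seed = NULL, conf = 0.95,
                         scale. = TRUE) {
  pca <- mediator_pcs(M_sel, k = k, scale. = scale.)
  rows <- lapply(seq_len(pca$k), function(j) {
    r <- mediate_single(x, pca$scores[, j], y, covariates,
                        n_boot = n_boot,
                        seed = if (is.null(seed)) NULL else
                          .child_seed(seed, j),
                        conf = conf)
    cbind(data.frame(pc = j, var_frac = pca$var_frac[j]), r)
  })
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 cumulative_prop = cumulative_mediation(results),
                 pca = pca),
            class = "pc_mediation")
}

#' Cumulative proportion mediated over significant PCs
#'
#' Sums `prop_mediated` over rows whose `significant` flag is set.  For
#' orthogonal PCs on the same data this is the lower bound on the joint
#' mediation proportion of the CpG set.
#'
#' @param rows data frame with `prop_mediated` and `significant` columns
#'   (as produced by [pc_mediation()]).
#' @return scalar cumulative proportion (0 when no PC is significant).
#' @export
cumulative_mediation <- function(rows) {
  sig <- rows$significant & !is.na(rows$prop_mediated)
  if (!any(sig)) return(0)
  sum(rows$prop_mediated[sig])
}
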