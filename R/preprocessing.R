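# Methylation and outcome preprocessing.
#
# Methylation: mean imputation -> 3xIQR winsorization -> residualization on
# cell proportions and plate/position batch labels.  Outcomes: 3xIQR
# outlier removal -> medication adjustment -> log transform (glucose, CRP).
# The two 3xIQR rules differ on purpose: methylation values are clamped to
# the fences (winsorized) while outcome values beyond the fences are
# removed.

#' Mean-impute missing methylation values
#'
#' Missing entries of each CpG column are replaced by that CpG's observed
#' mean; observed entries are untouched.
#'
#' @param M numeric matrix, participants x CpGs, possibly with `NA`.
#' @return matrix with no missing values.
#' @export
impute_mean <- function(M) {
  M <- as.matrix(M)
  all_missing <- colSums(!is.na(M)) == 0
  .assert(!any(all_missing),
          paste0("CpG column(s) with no observed values: ",
                 paste(utils::head(which(all_missing)), collapse = ", ")),
          "medewas_unprocessable_error")
  na_idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    M[na_idx] <- unname(colMeans(M, na.rm = TRUE)[na_idx[, 2]])
  }
  M
}

#' @keywords internal
#' @noRd
.iqr_fences <- function(x, k = 3) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Winsorize a vector at 3xIQR fences
#'
#' Values above `Q3 + k*IQR` are set to the fence; values below
#' `Q1 - k*IQR` likewise.  Quantiles use linear interpolation (type 7).
#' With a zero IQR both fences collapse to the quartile value and the
#' whole vector is clamped there.
#'
#' @param values numeric vector of length >= 4.
#' @param k fence multiplier, default 3.
#' @return winsorized vector; fence values attached as attribute `fences`.
#' @export
winsorize_iqr <- function(values, k = 3) {
  .assert(sum(!is.na(values)) >= 4,
          "need at least 4 non-missing values to winsorize",
          "medewas_degenerate_error")
  f <- .iqr_fences(values, k)
  out <- pmin(pmax(values, f["lower"]), f["upper"])
  attr(out, "fences") <- f
  out
}

#' Winsorize every CpG column of a methylation matrix
#'
#' @param M numeric matrix, participants x CpGs.
#' @param k fence multiplier, default 3.
#' @return matrix with each column winsorized at its own fences.
#' @export
winsorize_matrix <- function(M, k = 3) {
  M <- as.matrix(M)
  .assert(nrow(M) >= 4, "need at least 4 rows to winsorize",
          "medewas_degenerate_error")
  q <- apply(M, 2, stats::quantile, probs = c(0.25, 0.75), type = 7,
             names = FALSE)
  lower <- q[1, ] - k * (q[2, ] - q[1, ])
  upper <- q[2, ] + k * (q[2, ] - q[1, ])
  out <- pmin(pmax(M, rep(lower, each = nrow(M))),
              rep(upper, each = nrow(M)))
  dimnames(out) <- dimnames(M)
  out
}

#' Residualize methylation on cell proportions and batch labels
#'
#' Regresses each CpG on the cell-type proportions (one type dropped to
#' avoid the sum-to-one collinearity) plus plate and position factors,
#' entered as fixed-effect dummies, and returns the residuals re-centered
#' at each CpG's mean so values keep their beta-like scale.
#'
#' @param M numeric matrix, participants x CpGs (no missing values).
#' @param cells matrix of cell-type proportions, participants x types,
#'   rows summing to ~1; the last column is dropped internally.
#' @param plate,position_row,position_col optional batch factors.
#' @return matrix of re-centered residuals, same dimensions as `M`.
#' @export
residualize_methylation <- function(M, cells, plate = NULL,
                                    position_row = NULL,
                                    position_col = NULL) {
  M <- as.matrix(M)
  cells <- as.matrix(cells)
  .assert(nrow(cells) == nrow(M),
          "`cells` rows must match `M` rows", "medewas_dimension_error")
  .assert(!anyNA(M), "`M` must be imputed before residualization",
          "medewas_unprocessable_error")
  terms <- list(cells = cells[, -ncol(cells), drop = FALSE])
  add_factor <- function(f, name) {
    if (is.null(f)) return(NULL)
    f <- droplevels(as.factor(f))
    if (nlevels(f) < 2) return(NULL)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(name, levels(f)[-1])
    mm
  }
  design <- cbind(1, terms$cells,
                  add_factor(plate, "plate"),
                  add_factor(position_row, "row"),
                  add_factor(position_col, "col"))
  # constant covariates (e.g. identical cell proportions) are absorbed by
  # the intercept rather than flagged as collinear
  constant <- c(FALSE, apply(design[, -1, drop = FALSE], 2,
                             function(v) stats::var(v) == 0))
  design <- design[, !constant, drop = FALSE]
  qr_d <- qr(design)
  .assert(qr_d$rank == ncol(design),
          "rank-deficient nuisance design (collinear cell/batch terms)",
          "medewas_collinearity_error")
  resid <- qr.resid(qr_d, M)
  out <- sweep(resid, 2, colMeans(M), "+")
  dimnames(out) <- dimnames(M)
  out
}

#' Full methylation preprocessing pipeline
#'
#' Fixed order: mean imputation, 3xIQR winsorization per CpG, then
#' residualization on cell proportions and batch labels.
#'
#' @inheritParams residualize_methylation
#' @param k winsorization fence multiplier, default 3.
#' @return preprocessed methylation matrix.
#' @export
preprocess_methylation <- function(M, cells, plate = NULL,
                                   position_row = NULL,
                                   position_col = NULL, k = 3) {
  M <- impute_mean(M)
  M <- winsorize_matrix(M, k = k)
  residualize_methylation(M, cells, plate = plate,
                          position_row = position_row,
                          position_col = position_col)
}

#' Flag extreme outcome outliers at 3xIQR fences
#'
#' Unlike methylation winsorization, outcome values beyond the fences are
#' removed (set `NA` and flagged), not clamped.
#'
#' @param values numeric outcome vector of length >= 4.
#' @param k fence multiplier, default 3.
#' @return list with `values` (outliers `NA`), `excluded` (logical), and
#'   `fences`.
#' @export
remove_outliers_iqr <- function(values, k = 3) {
  .assert(sum(!is.na(values)) >= 4,
          "need at least 4 non-missing values for outlier fences",
          "medewas_degenerate_error")
  f <- .iqr_fences(values, k)
  excluded <- !is.na(values) & (values < f["lower"] | values > f["upper"])
  values[excluded] <- NA_real_
  list(values = values, excluded = excluded, fences = f)
}

# outcomes the pipeline knows, and which transform each receives
.known_outcomes <- c("BMI", "WC", "SBP", "DBP", "glucose", "TC", "LDL-C",
                     "HDL-C", "TG", "CRP")
.log_outcomes <- c("glucose", "CRP")

#' Adjust an outcome for medication use
#'
#' Standard pharmacological corrections: antihypertensive users get
#' SBP + 15 mm Hg and DBP + 10 mm Hg; statin users get LDL-C / 0.7 and
#' TC / 0.8.  HDL-C and TG are never adjusted.  Glucose values of
#' participants on diabetes medication are excluded rather than adjusted.
#' All other outcomes pass through unchanged.
#'
#' @param outcome outcome name, one of `BMI`, `WC`, `SBP`, `DBP`,
#'   `glucose`, `TC`, `LDL-C`, `HDL-C`, `TG`, `CRP`.
#' @param values numeric raw outcome vector.
#' @param antihypertensive,statin,diabetes_med logical medication flags
#'   per participant (recycled if length 1).
#' @return data frame with columns `raw`, `adjusted` (NA where excluded),
#'   `excluded`, `reason`.
#' @examples
#' adjust_medication("SBP", 120, antihypertensive = TRUE)$adjusted  # 135
#' @export
adjust_medication <- function(outcome, values,
                              antihypertensive = FALSE,
                              statin = FALSE,
                              diabetes_med = FALSE) {
  .assert(outcome %in% .known_outcomes,
          paste0("unknown outcome name: ", outcome),
          "medewas_schema_error")
  n <- length(values)
  antihypertensive <- rep_len(as.logical(antihypertensive), n)
  statin <- rep_len(as.logical(statin), n)
  diabetes_med <- rep_len(as.logical(diabetes_med), n)
  adjusted <- values
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  if (outcome == "SBP") {
    adjusted <- ifelse(antihypertensive, values + 15, values)
  } else if (outcome == "DBP") {
    adjusted <- ifelse(antihypertensive, values + 10, values)
  } else if (outcome == "LDL-C") {
    adjusted <- ifelse(statin, values / 0.7, values)
  } else if (outcome == "TC") {
    adjusted <- ifelse(statin, values / 0.8, values)
  } else if (outcome == "glucose") {
    excluded <- diabetes_med & !is.na(values)
    adjusted[excluded] <- NA_real_
    reason[excluded] <- "diabetes_medication"
  }
  data.frame(raw = values, adjusted = adjusted, excluded = excluded,
             reason = reason, stringsAsFactors = FALSE)
}

#' Log-transform skewed outcomes
#'
#' Natural log applied to glucose and CRP only; every other outcome is
#' returned unchanged.
#'
#' @param outcome outcome name.
#' @param values numeric vector; must be positive for log outcomes.
#' @return transformed vector.
#' @export
transform_outcome <- function(outcome, values) {
  .assert(outcome %in% .known_outcomes,
          paste0("unknown outcome name: ", outcome),
          "medewas_schema_error")
  if (!outcome %in% .log_outcomes) return(values)
  bad <- which(!is.na(values) & values <= 0)
  .assert(length(bad) == 0,
          paste0("non-positive value(s) for log outcome ", outcome,
                 " at index: ", paste(utils::head(bad), collapse = ", ")),
          "medewas_domain_error")
  log(values)
}

#' Full outcome preprocessing pipeline
#'
#' Fixed order: 3xIQR outlier removal on the raw values, medication
#' adjustment, then log transform where applicable.
#'
#' @inheritParams adjust_medication
#' @param k outlier fence multiplier, default 3.
#' @return data frame with `raw`, `adjusted`, `value` (final analysis
#'   value, `NA` where excluded), `transform` (`"log"` or
#'   `"identity"`), `excluded`, `reason`.
#' @export
preprocess_outcome <- function(outcome, values,
                               antihypertensive = FALSE,
                               statin = FALSE,
                               diabetes_med = FALSE, k = 3) {
  out <- remove_outliers_iqr(values, k = k)
  adj <- adjust_medication(outcome, out$values,
                           antihypertensive = antihypertensive,
                           statin = statin, diabetes_med = diabetes_med)
  data.frame(raw = values,
             adjusted = adj$adjusted,
             value = transform_outcome(outcome, adj$adjusted),
             transform = if (outcome %in% .log_outcomes) "log" else
               "identity",
             excluded = out$excluded | adj$excluded,
             reason = ifelse(out$excluded, "outlier_3iqr", adj$reason),
             stringsAsFactors = FALSE)
}
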