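# End-to-end pipeline orchestration.
#
# stress scoring -> methylation & outcome preprocessing -> total-effect
# gate -> mediation scan -> PC mediation -> de-biased LASSO mediation ->
# enrichment, with per-stage row accounting and deterministic seeding so a
# rerun with the same configuration reproduces every output bit for bit.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic study to analyze.
#' @param gate_p Model-1 p-value threshold gating the mediation stages,
#'   default 0.05.
#' @param q_threshold FDR threshold for mediating CpGs, default 0.05.
#' @param n_boot bootstrap iterations for PC mediation.
#' @param k_pcs number of PCs (`NULL` = default rule of [mediator_pcs()]).
#' @param adjust_smoking add smoking status to every covariate set
#'   (Model-2 style sensitivity analysis), default `FALSE`.
#' @param completeness_threshold stress-measure completeness rule,
#'   default 0.8.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), gate_p = 0.05,
                            q_threshold = 0.05, n_boot = 500L,
                            k_pcs = NULL, adjust_smoking = FALSE,
                            completeness_threshold = 0.8) {
  .assert(inherits(sim, "sim_config"), "`sim` must be a sim_config",
          "medewas_config_error")
  .assert(gate_p > 0 && gate_p < 1 && q_threshold > 0 && q_threshold < 1,
          "thresholds must lie in (0, 1)", "medewas_config_error")
  structure(list(sim = sim, gate_p = gate_p, q_threshold = q_threshold,
                 n_boot = as.integer(n_boot), k_pcs = k_pcs,
                 adjust_smoking = adjust_smoking,
                 completeness_threshold = completeness_threshold),
            class = "pipeline_config")
}

#' Run the full mediation pipeline on a synthetic study
#'
#' Executes every stage in fixed order and keeps a manifest of row counts
#' (input = analyzed + excluded at each stage) plus an audit table giving
#' each excluded participant exactly one machine-readable reason.  The
#' mediation stages run only when the Model-1 total effect passes the
#' configured gate.  All randomness derives from `config$sim$seed`, so
#' reruns are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage result is
#'   written as TSV.
#' @return list of class `pipeline_run` with elements `manifest` (stage
#'   accounting data frame), `audit` (exclusions), `scores`,
#'   `total_effects` (Models 1 and 2), `gate_passed`, `scan`, `pc`,
#'   `lasso`, `enrichment`, and `study` (the generated inputs).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  .assert(inherits(config, "pipeline_config"),
          "`config` must be a pipeline_config", "medewas_config_error")
  sim <- config$sim
  manifest <- list()
  note <- function(stage, n_in, n_excluded, n_out, detail = "") {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_excluded = n_excluded, n_out = n_out,
      detail = detail, stringsAsFactors = FALSE)
  }

  # 1. simulate
  study <- sim_study(sim)
  phen <- study$phenotype
  n0 <- nrow(phen)
  note("simulate", n0, 0L, n0,
       sprintf("seed=%d J=%d", sim$seed, sim$n_mediators))

  # 2. stress scoring (complete-case rule)
  scores <- stress_scores(study$stress_items,
                          completeness_threshold =
                            config$completeness_threshold)
  scored_ids <- scores$participant
  audit <- data.frame(participant = setdiff(phen$participant, scored_ids),
                      reason = "stress_incomplete",
                      stringsAsFactors = FALSE)
  note("stress_score", n0, n0 - length(scored_ids), length(scored_ids),
       "complete-case on all 12 measures")

  # 3. methylation preprocessing (all participants)
  meth <- study$methylation
  M <- preprocess_methylation(meth$beta, meth$cells, meth$plate,
                              meth$position_row, meth$position_col)
  note("preprocess_methylation", ncol(M), 0L, ncol(M),
       sprintf("clip_rate=%.4g", attr(meth$beta, "clip_rate")))

  # 4. outcome preprocessing: synthetic outcome is a generic continuous
  #    measure, so only the 3xIQR outlier rule applies
  scored_idx <- match(scored_ids, phen$participant)
  y_raw <- study$outcome[scored_idx]
  out_clean <- remove_outliers_iqr(y_raw)
  outlier_ids <- scored_ids[out_clean$excluded]
  if (length(outlier_ids) > 0) {
    audit <- rbind(audit, data.frame(participant = outlier_ids,
                                     reason = "outcome_outlier_3iqr",
                                     stringsAsFactors = FALSE))
  }
  keep <- !out_clean$excluded
  note("preprocess_outcome", length(scored_ids), sum(!keep), sum(keep),
       "3xIQR outlier removal")

  # 5. analysis set and covariates
  ids <- scored_ids[keep]
  idx <- match(ids, phen$participant)
  x <- scores$cumulative[keep]
  y <- out_clean$values[keep]
  covars <- phen[idx, c("age", "sex", "education", "stress_year",
                        paste0("pc", 1:10))]
  if (config$adjust_smoking) covars$smoking <- phen$smoking[idx]
  M_a <- M[idx, , drop = FALSE]
  note("analysis_set", n0, n0 - length(ids), length(ids),
       "stress-complete and outlier-free")

  # 6. total effects (Models 1 and 2)
  te1 <- fit_total_effect(y, x, covars, model = 1)
  te2 <- fit_total_effect(y, x, covars, smoking = phen$smoking[idx],
                          model = 2)
  total_effects <- rbind(te1, te2)
  gate_passed <- te1$p < config$gate_p
  note("total_effect_gate", 1L, as.integer(!gate_passed),
       as.integer(gate_passed),
       sprintf("model1_p=%.3g gate_p=%g", te1$p, config$gate_p))

  scan <- pc <- lasso <- enrich <- NULL
  if (gate_passed) {
    # 7. epigenome-wide mediation scan
    scan <- mediation_scan(x, M_a, y, covars,
                           total_effect = te1$estimate,
                           q_threshold = config$q_threshold)
    sig <- scan$results$significant
    note("mediation_scan", ncol(M_a), sum(scan$results$degenerate),
         sum(!scan$results$degenerate),
         sprintf("n_significant=%d", sum(sig)))

    sel_ids <- scan$results$mediator[sig]
    if (length(sel_ids) >= 1) {
      M_sel <- M_a[, sel_ids, drop = FALSE]
      # 8. PC mediation
      pc <- pc_mediation(x, M_sel, y, covars, k = config$k_pcs,
                         n_boot = config$n_boot,
                         seed = .child_seed(sim$seed, 11L))
      note("pc_mediation", pc$pca$k,
           pc$pca$k - sum(pc$results$significant),
           sum(pc$results$significant),
           sprintf("n_cpgs=%d cumulative_prop=%.4f", length(sel_ids),
                   pc$cumulative_prop))
      # 9. de-biased LASSO mediation
      sel_rows <- match(sel_ids, scan$results$mediator)
      lasso <- penalized_mediation(
        x, M_sel, y, covars,
        alpha = scan$results$alpha[sel_rows],
        p_alpha = scan$results$p_alpha[sel_rows],
        total_effect = te1$estimate,
        props = scan$null_proportions,
        seed = .child_seed(sim$seed, 12L),
        q_threshold = config$q_threshold)
      note("penalized_mediation", length(sel_ids),
           length(sel_ids) - sum(lasso$results$significant),
           sum(lasso$results$significant),
           sprintf("lambda=%.4g", lasso$lambda))
      # 10. enrichment against the non-mediating background
      enrich <- feature_enrichment(sel_ids, study$annotation)
      note("enrichment", nrow(enrich), 0L, nrow(enrich),
           sprintf("fisher exact, %d mediators vs %d background",
                   length(sel_ids), nrow(study$annotation) -
                     length(sel_ids)))
    } else {
      note("pc_mediation", 0L, 0L, 0L, "no mediating CpGs")
    }
  } else {
    note("mediation_scan", 0L, 0L, 0L, "gated out: model1 p >= gate_p")
  }

  manifest <- do.call(rbind, manifest)
  run <- structure(list(manifest = manifest, audit = audit,
                        scores = scores, total_effects = total_effects,
                        gate_passed = gate_passed, scan = scan, pc = pc,
                        lasso = lasso, enrichment = enrich,
                        study = study, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline(run, out_dir)
  run
}

#' Write all pipeline outputs as TSV
#'
#' @param run a `pipeline_run` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(run$manifest, p("manifest.tsv"))
  write_tsv(run$audit, p("audit.tsv"))
  write_tsv(run$scores, p("stress_scores.tsv"))
  write_tsv(run$total_effects, p("total_effects.tsv"))
  if (!is.null(run$scan)) {
    write_tsv(run$scan$results, p("mediation_scan.tsv"))
    write_tsv(run$scan$results[run$scan$results$significant, ],
              p("mediating_cpgs.tsv"))
  }
  if (!is.null(run$pc)) write_tsv(run$pc$results, p("pc_mediation.tsv"))
  if (!is.null(run$lasso)) write_tsv(run$lasso$results,
                                     p("lasso_mediation.tsv"))
  if (!is.null(run$enrichment)) write_tsv(run$enrichment,
                                          p("enrichment.tsv"))
  invisible(out_dir)
}
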