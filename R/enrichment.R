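# Genomic-feature and eQTM enrichment of mediating CpGs.
#
# Two-sided Fisher's exact tests compare the mediating CpGs against the
# non-mediating background for each annotation feature: enhancer, DHS,
# promoter (< 1.5 kb upstream of a TSS), CpG island, island shore
# (within 2 kb of an island) and shelf (2-4 kb), and eQTM membership.

#' Derive genomic feature flags from annotation distances
#'
#' Deterministic rules: `promoter` when the signed TSS distance lies in
#' `(-1500, 0]` bp (upstream negative); `cgi` when the island distance is
#' 0; `shore` when it lies in `(0, 2000]` bp; `shelf` in `(2000, 4000]`
#' bp.  Missing distances leave the corresponding flags `NA`, excluding
#' those CpGs from that feature's test.
#'
#' @param annotation data frame with at least `mediator`, `dist_tss`
#'   (signed, upstream negative), `dist_cgi` (absolute bp); optionally
#'   `enhancer`, `dhs`, `eqtm` logical columns which pass through.
#' @return the annotation with logical columns `promoter`, `cgi`,
#'   `shore`, `shelf` added.
#' @examples
#' a <- data.frame(mediator = "cg1", dist_tss = -1000, dist_cgi = 3000)
#' derive_feature_flags(a)[, c("promoter", "shore", "shelf")]
#' @export
derive_feature_flags <- function(annotation) {
  .assert(all(c("dist_tss", "dist_cgi") %in% names(annotation)),
          "`annotation` needs `dist_tss` and `dist_cgi` columns",
          "medewas_schema_error")
  d_tss <- annotation$dist_tss
  d_cgi <- abs(annotation$dist_cgi)
  annotation$promoter <- d_tss > -1500 & d_tss <= 0
  annotation$cgi <- d_cgi == 0
  annotation$shore <- d_cgi > 0 & d_cgi <= 2000
  annotation$shelf <- d_cgi > 2000 & d_cgi <= 4000
  annotation
}

#' Fisher's exact enrichment test for one feature
#'
#' Builds the 2x2 table (mediator vs background by feature presence) and
#' tests it with a two-sided Fisher's exact test (minimum-likelihood
#' two-sided rule: summing all tables with probability at most that of
#' the observed table).  The reported odds ratio is the sample OR
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe 0.5
#' correction is applied to the OR display only (flagged), never to the
#' p-value.
#'
#' @param mediator_flags logical vector of feature flags for the
#'   mediating CpGs (`NA` dropped).
#' @param background_flags logical vector for the background CpGs.
#' @param feature feature name carried into the result.
#' @return one-row data frame: `feature`, cell counts `med_yes`,
#'   `med_no`, `bg_yes`, `bg_no`, `odds_ratio`, `haldane` (correction
#'   flag), `p`.
#' @export
fisher_enrichment <- function(mediator_flags, background_flags,
                              feature = "feature") {
  m <- mediator_flags[!is.na(mediator_flags)]
  b <- background_flags[!is.na(background_flags)]
  .assert(length(m) > 0 && length(b) > 0,
          "both mediator and background groups must be non-empty",
          "medewas_degenerate_error")
  tab <- matrix(c(sum(m), length(m) - sum(m),
                  sum(b), length(b) - sum(b)),
                2, 2, byrow = TRUE,
                dimnames = list(c("mediator", "background"),
                                c("yes", "no")))
  .assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
          "degenerate 2x2 table: empty margin", "medewas_degenerate_error")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  a <- tab[1, 1]; bb <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((bb + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (bb * cc)
  }
  data.frame(feature = feature, med_yes = a, med_no = bb,
             bg_yes = cc, bg_no = d, odds_ratio = or,
             haldane = haldane, p = ft$p.value,
             stringsAsFactors = FALSE)
}

#' eQTM enrichment of mediating CpGs
#'
#' Fisher's exact test on the eQTM flag, mediating versus non-mediating
#' CpGs, answering whether the mediators are more likely to be expression
#' quantitative trait methylation sites.
#'
#' @param mediator_ids character vector of mediating CpG ids.
#' @param annotation annotation table with `mediator` and logical `eqtm`
#'   columns covering both mediators and background.
#' @return one-row data frame as in [fisher_enrichment()].
#' @export
eqtm_enrichment <- function(mediator_ids, annotation) {
  .assert("eqtm" %in% names(annotation),
          "`annotation` needs an `eqtm` column", "medewas_schema_error")
  is_med <- annotation$mediator %in% mediator_ids
  .assert(any(is_med), "no mediating CpGs found in the annotation",
          "medewas_degenerate_error")
  fisher_enrichment(annotation$eqtm[is_med], annotation$eqtm[!is_med],
                    feature = "eqtm")
}

#' Enrichment of mediating CpGs across all genomic features
#'
#' Runs [fisher_enrichment()] for each feature flag (enhancer, DHS,
#' promoter, CGI, shore, shelf — whichever are present) plus
#' [eqtm_enrichment()], mediators versus all other annotated CpGs.
#'
#' @param mediator_ids character vector of mediating CpG ids.
#' @param annotation annotation table (feature flags derived with
#'   [derive_feature_flags()] if absent).
#' @param features feature columns to test; defaults to those available.
#' @return data frame, one row per feature.
#' @export
feature_enrichment <- function(mediator_ids, annotation,
                               features = NULL) {
  if (!all(c("promoter", "cgi", "shore", "shelf") %in% names(annotation)) &&
      all(c("dist_tss", "dist_cgi") %in% names(annotation))) {
    annotation <- derive_feature_flags(annotation)
  }
  if (is.null(features)) {
    features <- intersect(c("dhs", "enhancer", "promoter", "cgi",
                            "shore", "shelf"),
                          names(annotation))
  }
  is_med <- annotation$mediator %in% mediator_ids
  .assert(any(is_med), "no mediating CpGs found in the annotation",
          "medewas_degenerate_error")
  rows <- lapply(features, function(f) {
    fisher_enrichment(annotation[[f]][is_med], annotation[[f]][!is_med],
                      feature = f)
  })
  if ("eqtm" %in% names(annotation)) {
    rows <- c(rows, list(eqtm_enrichment(mediator_ids, annotation)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
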