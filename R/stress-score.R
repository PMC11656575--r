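# Cumulative psychosocial-stress scoring.
#
# Item-level responses are rolled up to measure scores (with an 80%
# completeness rule and proration), z-standardized, summed within domains,
# re-standardized, summed across the six domains, and re-standardized once
# more.  The final cumulative z-score is the exposure used everywhere
# downstream.

#' Default stress battery definition
#'
#' Twelve measures across six domains: acute life events (lifetime traumas,
#' 7 items; recent stressful life events, 6 items), financial stress
#' (financial strain, 2; lack of financial autonomy, 2), neighborhood
#' stress (4), relationship stress (spouse, children, other family,
#' friends; 4 items each), lifetime discrimination (everyday
#' discrimination, 5; major discriminatory events, 6), and childhood
#' adversity (4).
#'
#' @return data frame with columns `measure`, `domain`, `n_items`.
#' @export
stress_battery <- function() {
  data.frame(
    measure = c("lifetime_traumas", "recent_life_events",
                "financial_strain", "financial_autonomy",
                "neighborhood_stress",
                "spouse_strain", "child_strain", "family_strain",
                "friend_strain",
                "everyday_discrimination", "major_discrimination",
                "childhood_adversity"),
    domain = c("acute_life_events", "acute_life_events",
               "financial", "financial",
               "neighborhood",
               "relationship", "relationship", "relationship",
               "relationship",
               "discrimination", "discrimination",
               "childhood_adversity"),
    n_items = c(7L, 6L, 2L, 2L, 4L, 4L, 4L, 4L, 4L, 5L, 6L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Score one stress measure with a completeness rule
#'
#' Participants who answered at least `completeness_threshold` of the
#' measure's items receive the mean of their answered items rescaled to the
#' full-item (sum) scale, i.e. prorated as `mean(answered) * n_items`.
#' Participants below the threshold are scored missing.
#'
#' @param items numeric matrix, participants x items; `NA` marks an
#'   unanswered item.
#' @param n_items number of items the measure is defined to have; defaults
#'   to `ncol(items)`.
#' @param completeness_threshold minimum answered fraction in (0, 1];
#'   default 0.8.
#' @param item_signs optional `+1`/`-1` vector applied to items before
#'   scoring (reverse coding).
#' @return numeric vector of raw measure scores with `NA` for incomplete
#'   participants.
#' @examples
#' m <- rbind(c(1, 2, NA, 2), c(2, 2, 2, 2))
#' score_measure(m)  # first row 75% complete -> NA
#' @export
score_measure <- function(items, n_items = ncol(items),
                          completeness_threshold = 0.8,
                          item_signs = NULL) {
  items <- as.matrix(items)
  .assert(completeness_threshold > 0 && completeness_threshold <= 1,
          "`completeness_threshold` must lie in (0, 1]",
          "medewas_config_error")
  .assert(ncol(items) == n_items,
          sprintf("measure has %d item columns but is defined with %d items",
                  ncol(items), n_items),
          "medewas_schema_error")
  if (!is.null(item_signs)) {
    .assert(length(item_signs) == n_items &&
              all(item_signs %in% c(-1, 1)),
            "`item_signs` must be +1/-1 per item", "medewas_schema_error")
    items <- sweep(items, 2, item_signs, "*")
  }
  answered <- rowSums(!is.na(items))
  score <- rowMeans(items, na.rm = TRUE) * n_items
  score[answered / n_items < completeness_threshold] <- NA_real_
  score[answered == 0] <- NA_real_
  score
}

#' Standardize a vector to a z-score
#'
#' `(v - mean) / SD` over non-missing values using the sample SD
#' (n - 1 denominator); missing values propagate.
#'
#' @param values numeric vector, possibly with `NA`.
#' @return z-scored vector of the same length.
#' @export
z_standardize <- function(values) {
  obs <- values[!is.na(values)]
  .assert(length(obs) >= 2,
          "need at least 2 non-missing values to standardize",
          "medewas_degenerate_error")
  s <- stats::sd(obs)
  .assert(s > 0, "cannot standardize a constant vector (zero SD)",
          "medewas_degenerate_error")
  (values - mean(obs)) / s
}

#' Aggregate measure z-scores into a domain z-score
#'
#' Sums the constituent measures' z-scores and re-standardizes the sum.
#' Participants missing any constituent measure are excluded
#' (complete-case): their domain score is `NA`.
#'
#' @param measure_z numeric matrix or data frame, participants x measures,
#'   of z-scores for one domain.
#' @return numeric domain z-score vector.
#' @export
aggregate_domain <- function(measure_z) {
  measure_z <- as.matrix(measure_z)
  total <- rowSums(measure_z)  # NA if any constituent missing
  z_standardize(total)
}

#' Combine domain z-scores into the cumulative stress score
#'
#' Sums the domain z-scores and re-standardizes; the result is the
#' standardized cumulative stress exposure.
#'
#' @param domain_z matrix or data frame, participants x domains.
#' @param n_domains number of domains the battery is configured with
#'   (default 6); fewer columns is a configuration error.
#' @return numeric cumulative z-score vector.
#' @export
cumulative_score <- function(domain_z, n_domains = 6L) {
  domain_z <- as.matrix(domain_z)
  .assert(ncol(domain_z) >= n_domains,
          sprintf("expected %d domains, got %d", n_domains, ncol(domain_z)),
          "medewas_config_error")
  z_standardize(rowSums(domain_z))
}

#' Build cumulative stress scores from an item-response table
#'
#' Full scoring pipeline: per-measure proration and completeness, the
#' complete-case rule (participants missing any measure are dropped),
#' z-standardization of measures over the complete-case set, domain
#' aggregation, and the cumulative score.
#'
#' @param stress_items long table with columns `participant`, `measure`,
#'   `item`, `response` (as produced by [sim_cohort()]).
#' @param battery battery definition; default [stress_battery()].
#' @param completeness_threshold per-measure completeness fraction,
#'   default 0.8.
#' @return data frame with one row per complete-case participant:
#'   `participant`, one `z_<measure>` column per measure, one `zd_<domain>`
#'   column per domain, and `cumulative` (the exposure).
#' @export
stress_scores <- function(stress_items, battery = stress_battery(),
                          completeness_threshold = 0.8) {
  .assert(all(c("participant", "measure", "item", "response") %in%
                names(stress_items)),
          "`stress_items` needs participant/measure/item/response columns",
          "medewas_schema_error")
  unknown <- setdiff(unique(stress_items$measure), battery$measure)
  .assert(length(unknown) == 0,
          paste0("unknown measure id(s): ", paste(unknown, collapse = ", ")),
          "medewas_schema_error")
  participants <- sort(unique(stress_items$participant))
  raw <- matrix(NA_real_, length(participants), nrow(battery),
                dimnames = list(participants, battery$measure))
  for (m in seq_len(nrow(battery))) {
    rows <- stress_items[stress_items$measure == battery$measure[m], ]
    .assert(nrow(rows) > 0,
            paste0("no responses for measure ", battery$measure[m]),
            "medewas_schema_error")
    k <- battery$n_items[m]
    .assert(max(rows$item) <= k,
            sprintf("measure %s has item index > %d",
                    battery$measure[m], k),
            "medewas_schema_error")
    wide <- matrix(NA_real_, length(participants), k,
                   dimnames = list(participants, NULL))
    wide[cbind(match(rows$participant, participants), rows$item)] <-
      rows$response
    raw[, m] <- score_measure(wide, n_items = k,
                              completeness_threshold = completeness_threshold)
  }
  complete <- stats::complete.cases(raw)
  .assert(sum(complete) >= 2,
          "fewer than 2 participants pass the complete-case rule",
          "medewas_degenerate_error")
  raw <- raw[complete, , drop = FALSE]
  measure_z <- apply(raw, 2, z_standardize)
  domains <- unique(battery$domain)
  domain_z <- sapply(domains, function(d) {
    cols <- battery$measure[battery$domain == d]
    aggregate_domain(measure_z[, cols, drop = FALSE])
  })
  cumulative <- cumulative_score(domain_z, n_domains = length(domains))
  out <- data.frame(participant = rownames(raw), stringsAsFactors = FALSE)
  colnames(measure_z) <- paste0("z_", colnames(measure_z))
  colnames(domain_z) <- paste0("zd_", domains)
  out <- cbind(out, as.data.frame(measure_z), as.data.frame(domain_z))
  out$cumulative <- cumulative
  rownames(out) <- NULL
  out
}
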