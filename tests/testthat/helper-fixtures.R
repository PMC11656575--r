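# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# small complete stress-item table: `patterns` is a list of per-measure
# response vectors per participant (recycled); NA marks missing items
make_items <- function(n, battery = stress_battery(), seed = 1,
                       missing_rate = 0) {
  cfg <- sim_config(n_participants = n, n_mediators = 10,
                    item_missing_rate = missing_rate, seed = seed)
  sim_cohort(cfg)$stress_items
}

# quantile type-7 oracle written from the interpolation formula, kept
# independent of stats::quantile
q7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# two-sided Fisher p by explicit hypergeometric enumeration
# (minimum-likelihood rule), independent of stats::fisher.test
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# BH step-up oracle independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
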