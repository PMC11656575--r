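---
title: "Methods: high-dimensional epigenome-wide mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-dimensional epigenome-wide mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the pipeline answers

Chronic psychosocial stress is an established determinant of
cardiometabolic risk, and DNA methylation responds to both stress and
cardiometabolic processes.  The pipeline asks, for a cohort with a
cumulative stress score $X$, blood DNA methylation beta values $M_j$
($j = 1, \dots, J$, typically $10^3$–$10^6$ CpGs), and a continuous
cardiometabolic outcome $Y$: which CpGs transmit part of the effect of
$X$ on $Y$, and how much of the total effect do they carry jointly?

The working models per CpG are the classical linear mediation pair

$$M_j = \alpha_{0,j} + \alpha_j X + \alpha_{C,j}^T C + \varepsilon_{M,j},
\qquad
Y = \beta_{0,j} + \beta_{X,j} X + \beta_j M_j + \beta_{C,j}^T C +
\varepsilon_{Y,j},$$

with covariates $C$ (age, sex, education, measurement year, ancestry
PCs, optionally smoking and fasting status).  The mediation effect of
CpG $j$ is the product $\alpha_j \beta_j$; the proportion of the total
effect it carries is $\alpha_j \beta_j / \tau$, where $\tau$ is the
total-effect coefficient of $X$ in the outcome model without mediators.

## Stress scoring

The exposure is built from item-level survey responses in twelve
measures across six domains (acute life events, financial strain,
neighborhood stress, relationship strain, lifetime discrimination,
childhood adversity).  Rules, in order:

* a measure counts as complete when at least 80% of its items were
  answered (the `>=` convention at exactly 80%); complete measures are
  prorated, `mean(answered items) * n_items`, so partially answered
  measures stay on the full-item sum scale;
* participants missing any measure are excluded (complete-case rule);
  all standardization happens on the complete-case set;
* measures are z-scored (sample SD, $n-1$), summed within domain,
  re-standardized, summed across the six domains, and re-standardized
  once more.  The result has mean 0 and SD 1 by construction, so every
  downstream coefficient is per SD of cumulative stress.

Z-scoring makes the score invariant to affine rescaling of any raw
measure, which the test suite checks explicitly.

## Preprocessing

Methylation (fixed order, each step idempotent):

1. **mean imputation** per CpG;
2. **winsorization** at Tukey-style fences $Q_1 - 3\,\mathrm{IQR}$ and
   $Q_3 + 3\,\mathrm{IQR}$ (type-7 quantiles, the interpolation default;
   logged here so an alternative rule can be compared);
3. **residualization** on estimated white-blood-cell proportions (one
   type dropped against the sum-to-one collinearity) plus sample plate
   and position.  Plate and position enter as fixed-effect dummies
   rather than random effects: per-CpG OLS residuals are deterministic,
   fast at $10^5$ CpGs, and equivalent in expectation for balanced
   designs.  Residuals are re-centered at the CpG mean so values keep a
   beta-like scale; re-centering cannot change any downstream slope.

Outcomes: extreme values beyond the same $3\times$IQR fences are
**removed** (methylation is clamped, outcomes are dropped — the
asymmetry is deliberate and tested); medication adjustments follow the
standard pharmacological constants (SBP $+15$, DBP $+10$ mm Hg under
antihypertensives; LDL-C$/0.7$, TC$/0.8$ under statins; HDL-C and TG
never adjusted; glucose under diabetes medication excluded rather than
adjusted); glucose and CRP are natural-log transformed.

Residualization matters more than it may look: in the generator (and in
real blood data) cell composition and batch affect *many* CpGs at once,
and any outcome driven by methylation inherits those shared components.
Without pre-adjustment the per-CpG outcome regressions are confounded
epigenome-wide; with it the null t-statistics are calibrated, which the
acceptance suite verifies.

## The composite-null scan

$H_{0,j}: \alpha_j \beta_j = 0$ is a union of three configurations —
$(\alpha = 0, \beta = 0)$, $(\alpha \neq 0, \beta = 0)$,
$(\alpha = 0, \beta \neq 0)$ — so the MaxP statistic
$t_j = \max(p_{\alpha_j}, p_{\beta_j})$ is not uniform under the null:
under the double null its CDF is $t^2$, under either single null
(with the non-null path well powered) it is $t$.  Treating $t$ as a
p-value is conservative exactly when most CpGs are doubly null, which
is why the naive MaxP test loses power epigenome-wide.

The correction evaluates the mixture CDF at the observed $t$,

$$p_{\mathrm{corr}}(t) =
\frac{\pi_{01} t + \pi_{10} t + \pi_{00} t^2}
     {\pi_{01} + \pi_{10} + \pi_{00}},$$

with the three null proportions estimated by Storey-type tail
estimators applied to each p-value series at $\lambda = 0.5$
($\hat\pi_{\alpha 0} = \#\{p_\alpha > \lambda\}/(J(1-\lambda))$,
truncated to 1; likewise for $\beta$) and combined under
cross-independence of the two null memberships.  This is the simplest
estimator that satisfies the composite-null correction; it sits behind
the `null_proportions` interface so a different estimator can be
swapped in.  The finite-sample extreme-tail quantile adjustment that
some implementations add on top of the parametric mixture is not
reproduced; at realistic $J$ and a $q < 0.05$ threshold the mixture CDF
dominates behavior, and the approximation is recorded here.

BH FDR is applied to the corrected p-values; CpGs with $q < 0.05$ are
the mediating set.  Corrected p-values are uniform *averaged over the
null mixture*, not conditionally per category: single-null CpGs are
locally anti-conservative and doubly null CpGs hyper-conservative, in
proportions that cancel.  BH control therefore holds marginally, and
the acceptance suite measures the realized false-discovery proportion
directly against the generator's truth table.

Implementation notes: both regressions for all $J$ CpGs are computed
from one QR decomposition of the $[1, C, X]$ design via
Frisch–Waugh–Lovell residualization, giving estimates, SEs and exact
t-test p-values identical to a per-CpG `lm()` loop (tested to 1e-10) at
about five orders of magnitude less work.  Mediator columns that are
constant or collinear with the design are flagged `degenerate`, skipped
with a log message, and excluded from significance.  Report rows keep
the input CpG order, so MaxP ties break by stable mediator order.

## PC-based cumulative mediation

The per-CpG scan cannot sum mediation over correlated CpGs.  The
selected CpGs are therefore reduced to principal components — centered,
unit-variance scaled by default (beta-value variances span orders of
magnitude; scaling is an assumption recorded here), signs fixed by
making the largest-magnitude loading positive — and each PC score is
run through a bootstrap mediation analysis: point ACME
$\hat a \hat b$ from the two linear models, percentile CIs from
resampling participants with replacement (a resample with constant
exposure is redrawn and counted), significance = the 95% CI excluding
zero, and the proportion mediated $\widehat{\mathrm{ACME}}/\hat\tau$
with $\hat\tau$ re-estimated in each resample.  In a linear
no-interaction model the product estimator equals total-minus-direct
exactly on any dataset, which the suite asserts to 1e-10.  Defaults:
10 PCs, 5 when fewer than 10 CpGs were selected; 10,000 bootstrap
iterations for analysis use, smaller values in the tests (sizes below).
Percentile rather than BCa intervals: the simplest construction
consistent with a nonparametric bootstrap, and configurable.

The cumulative proportion sums per-PC proportions over significant PCs.
Because the PCs are sample-orthogonal, this approximates a lower bound
on the joint mediation of the CpG set.  Two caveats are worth stating
plainly.  First, PCs are orthogonal marginally but not after
conditioning on $X$, so per-PC contributions are not an exact
decomposition; when the exposure-effect direction is spread across
several near-degenerate eigenvectors, part of the mediated signal can
land on individually non-significant PCs and the cumulative estimate
loses it (it errs low, consistent with the lower-bound reading).
Second, with strongly correlated mediators the leading PC absorbs the
shared signal and the bound is tight.  Both regimes are exercised in
the acceptance suite with known joint proportions.

## De-biased LASSO multivariable mediation

The scan's $\hat\beta_j$ ignores co-mediators.  For the selected set
(tens of CpGs, far fewer than $n$) the outcome is refit jointly:
LASSO on $[X, M_{\mathrm{sel}}, C]$ with only the CpG columns
penalized — exposure and covariates are design variables, not selection
targets — and $\lambda$ chosen by seed-fixed 10-fold CV at the 1-SE
rule.  Each CpG coefficient is then de-biased by the
node-wise-regression (desparsified) correction
$\tilde b_j = \hat b_j + z_j^T(y - D\hat b)/z_j^T D_j$, where $z_j$ is
the residual of a node-wise LASSO of column $j$ on the remaining
columns; SEs are $\hat\sigma \lVert z_j \rVert_2 / |z_j^T D_j|$ with
$\hat\sigma$ from the penalized fit.  At $\lambda = 0$ the correction
vanishes against the OLS residual and the estimates equal multivariable
OLS exactly (tested to 1e-6); at CV-selected $\lambda$ the de-biased
estimates are unbiased to within 10% on nonzero coefficients in the
acceptance simulations.  Designs with $p \ge n$ are rejected with a
pointer to screening — the intended regime is the scan-selected set.

Joint significance pairs each CpG's scan-side $p_\alpha$ with its
adjusted $p_\beta$ and reuses the same mixture-CDF correction and BH
step.  Null proportions are re-estimated on the selected set only when
it holds at least 100 CpGs; smaller sets (the usual case) inherit the
genome-wide proportions, because tail estimators are unstable below
that size.

## Enrichment

Two-sided Fisher's exact tests compare mediating CpGs against the
non-mediating background for enhancer, DHS, promoter, CpG-island,
shore, shelf, and eQTM membership.  Feature rules: promoter = signed
TSS distance in $(-1500, 0]$ bp (upstream negative); island = CGI
distance 0; shore $(0, 2000]$ bp; shelf $(2000, 4000]$ bp.  The
two-sided p-value uses the minimum-likelihood convention (sum of all
tables with probability at most the observed table's), which the suite
verifies against full hypergeometric enumeration over every table
symmetry class with total up to 40.  The reported odds ratio is the
sample $(ad)/(bc)$; a Haldane–Anscombe 0.5 correction is applied to the
OR display only when a cell is zero, never to the p-value.  The
annotation is a user-supplied BED-like table; the package ships only a
synthetic annotation generator (flagged synthetic) for tests and demos.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
every statistical claim in this package is verified under.

* **Exposure and covariates.** Item responses for all twelve measures
  are drawn from binomials whose success probability rises with a
  latent standardized stress factor; age, education, and smoking
  correlate with the factor at a configurable level (default 0.2);
  0.5% of item responses are missing so the completeness rule is
  exercised.  The exposure that drives methylation and outcome is the
  *scored* cumulative construct (prorated for everyone, standardized
  over the cohort), not the latent factor, so the truth table's
  $\alpha_j$ is exactly the coefficient the analysis models estimate.
  Real data differ here: with a noisy measured exposure, residual
  confounding through the unmeasured part of the construct can
  masquerade as mediation.  That attenuation regime is deliberately not
  part of the default conditions, and passing tests say nothing about
  it.
* **Mediators.** Each CpG draws a composite-null category from
  `null_mix`; the latent signal $0.5 + \alpha_j X + $ cell and plate
  nuisance terms $+$ block-exchangeable residuals is clipped to
  $[0.001, 0.999]$ rather than squashed through a logit, so
  $\alpha_j$ stays the exact linear coefficient outside the clipped
  tail; the realized clip rate is reported on the matrix (zero at the
  defaults).  Blocks of 10 consecutive CpGs share residual correlation
  0.4, emulating neighboring-CpG correlation.
* **Outcome.** $Y = \theta X + \sum_j \beta_j M_j + $ small age and
  smoking terms $+$ Gaussian noise.
* **Defaults.** $n = 500$, $J = 2000$,
  `null_mix` $= (0.975, 0.010, 0.005, 0.010)$, $\alpha = 0.04$
  methylation units per SD stress, $\beta = 5$ outcome units per
  methylation unit, direct effect $0.5$, mediator residual SD $0.05$,
  outcome noise SD 1.  Signal this sparse is the realistic regime for
  an EWAS (published scans find tens of mediators among $~8 \times
  10^5$ CpGs); effect sizes are chosen so single CpGs are detectable at
  $n = 500$, which published per-CpG effects at these sample sizes are
  not — the defaults are calibrated for testability, not for effect
  realism, and no reported magnitude should be read as a biological
  estimate.
* **Seeding.** One integer seed drives every stage through fixed
  offsets; the whole generated study and the whole pipeline output are
  bit-reproducible, which the suite checks by file checksum.

Features of real data the generator does not emulate: array-level
artifacts (detection failures, cross-reactive probes, dye bias),
non-Gaussian methylation residuals, exposure measurement error (above),
long-range correlation beyond exchangeable blocks, and
survey-sampling weights.

## Simulation sizes used by the tests

The statistical acceptance checks run at: composite-null calibration
$J = 10{,}000$, $n = 500$, complete-null uniformity on one dataset and
the mixture $(0.90, 0.045, 0.045, 0.01)$ over 150 replicates (false
discoveries there are rare events, so the mean false-discovery
proportion needs that many replicates for a stable estimate);
single-mediator recovery at $n = 2668$ with 200 replicates and 500
bootstrap iterations; PC lower-bound and recovery arms at $n = 500$,
10 mediators, 100 replicates, 200 bootstrap iterations; de-biased
LASSO at $n = 2000$, $p = 10$, 200 replicates; Fisher enumeration
exhaustive to total 40; end-to-end runs at the generator defaults.
The acceptance script recomputes the same quantities at moderately
reduced replicate counts (30–100) chosen as a sensible desk-scale
budget; both sizes are the package's own choices.

Under the dense mixture used in the calibration study, a useful
identifiability yardstick: with $K$ mediators carrying equal outcome
effects, the per-CpG outcome t-statistic is bounded by
$\sqrt{n/(K-1)}$ no matter how large $\beta$ is, because the other
mediators act as irreducible outcome noise.  At $n = 500$ and
$K = 550$ that bound is $\approx 0.95$, so per-CpG power there comes
only from the correction's finite-sample advantage near the BH
threshold — which is exactly what the power comparison against naive
MaxP measures.

## Known limitations

* The Storey estimator can truncate a single-null proportion to zero in
  very sparse regimes, locally inflating that category's corrected
  p-values; the mixture remains marginally calibrated but per-category
  conditional error is not controlled.
* Under block correlation, a null CpG sharing a block with a true
  outcome-associated CpG inherits part of its signal (the scan is
  marginal by design); the truth-table FDR in the acceptance suite
  includes these leakage discoveries, so the measured control is the
  honest, slightly pessimistic number.
* The PC cumulative estimate is a heuristic lower bound, not an
  identified estimand; see the caveats above.
* Linear, no-interaction mediation throughout; no exposure-mediator
  interactions, no sensitivity analysis for sequential ignorability,
  and with exposure, mediators, and outcome measured concurrently the
  causal direction is assumed, not established.
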