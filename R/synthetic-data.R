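# Synthetic cohort generator.
#
# Emulates the statistical structure the mediation pipeline assumes: a
# standardized continuous exposure built from item-level stress responses,
# high-dimensional methylation mediators in [0,1] with block correlation and
# cell-type/batch nuisance signal, and a continuous outcome with known direct
# and mediated effects.  A truth table records each mediator's composite-null
# category so false discovery rates, power, and effect recovery can be
# measured exactly.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator and validates it.
#' The composite-null mixture `null_mix` gives the proportions of mediators
#' in each of the four categories of the mediation null
#' \eqn{H_0: \alpha\beta = 0}:
#' `pi00` (\eqn{\alpha = 0, \beta = 0}), `pi10` (\eqn{\alpha \ne 0, \beta = 0}),
#' `pi01` (\eqn{\alpha = 0, \beta \ne 0}) and `pi11` (both nonzero; the only
#' true mediators).
#'
#' Mediators are generated on a latent Gaussian scale centered at 0.5 and
#' clipped into `[0.001, 0.999]`, so `alpha_effect` remains the exact
#' linear-model coefficient except in the (rare) clipped tail; the clip rate
#' is reported as an attribute of the generated matrix.  Residuals are
#' block-exchangeable: within blocks of `block_size` consecutive CpGs the
#' residual correlation is `block_rho`.
#'
#' @param n_participants number of participants (> 0).
#' @param n_mediators number of CpG mediators (> 0).
#' @param null_mix numeric length-4 vector `(pi00, pi10, pi01, pi11)`
#'   summing to 1.
#' @param alpha_effect exposure effect on each non-null mediator
#'   (methylation units per SD of exposure).
#' @param beta_effect mediator effect on the outcome (outcome units per
#'   methylation unit).
#' @param direct_effect exposure effect on the outcome not passing through
#'   any mediator.
#' @param block_size,block_rho mediator residual correlation structure;
#'   `block_rho` must lie in `[0, 1)`.
#' @param n_cell_types number of white-blood-cell types whose proportions
#'   act as nuisance covariates.
#' @param cell_effect_scale SD of the per-CpG cell-type and plate nuisance
#'   coefficients (methylation units).
#' @param n_plates number of sample plates (batch labels).
#' @param noise_sd_mediator residual SD of each mediator (> 0).
#' @param noise_sd_outcome residual SD of the outcome (> 0).
#' @param exposure_covariate_cor correlation between the latent exposure and
#'   the generated covariates (age, education, smoking).
#' @param item_missing_rate probability that any single stress item response
#'   is missing.
#' @param seed integer seed; one seed drives every stage of generation
#'   through fixed offsets.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_participants = 50, n_mediators = 100, seed = 1)
#' @export
sim_config <- function(n_participants = 500L,
                       n_mediators = 2000L,
                       null_mix = c(pi00 = 0.975, pi10 = 0.010,
                                    pi01 = 0.005, pi11 = 0.010),
                       alpha_effect = 0.04,
                       beta_effect = 5,
                       direct_effect = 0.5,
                       block_size = 10L,
                       block_rho = 0.4,
                       n_cell_types = 6L,
                       cell_effect_scale = 0.03,
                       n_plates = 4L,
                       noise_sd_mediator = 0.05,
                       noise_sd_outcome = 1,
                       exposure_covariate_cor = 0.2,
                       item_missing_rate = 0.005,
                       seed = 1L) {
  .assert(length(n_participants) == 1 && is.finite(n_participants) &&
            n_participants >= 1,
          "`n_participants` must be a positive count",
          "medewas_config_error")
  .assert(length(n_mediators) == 1 && is.finite(n_mediators) &&
            n_mediators >= 1,
          "`n_mediators` must be a positive count", "medewas_config_error")
  .assert(length(null_mix) == 4 && all(is.finite(null_mix)) &&
            all(null_mix >= 0),
          "`null_mix` must be four non-negative proportions",
          "medewas_config_error")
  .assert(abs(sum(null_mix) - 1) <= 1e-12,
          "`null_mix` must sum to 1 (within 1e-12)", "medewas_config_error")
  .assert(block_rho >= 0 && block_rho < 1,
          "`block_rho` must lie in [0, 1)", "medewas_config_error")
  .assert(noise_sd_mediator > 0 && noise_sd_outcome > 0,
          "noise SDs must be positive", "medewas_config_error")
  .assert(block_size >= 1, "`block_size` must be >= 1",
          "medewas_config_error")
  .assert(n_cell_types >= 2, "`n_cell_types` must be >= 2",
          "medewas_config_error")
  .assert(n_plates >= 1, "`n_plates` must be >= 1", "medewas_config_error")
  .assert(item_missing_rate >= 0 && item_missing_rate < 1,
          "`item_missing_rate` must lie in [0, 1)", "medewas_config_error")
  names(null_mix) <- c("pi00", "pi10", "pi01", "pi11")
  structure(list(
    n_participants = as.integer(n_participants),
    n_mediators = as.integer(n_mediators),
    null_mix = null_mix,
    alpha_effect = alpha_effect,
    beta_effect = beta_effect,
    direct_effect = direct_effect,
    block_size = as.integer(block_size),
    block_rho = block_rho,
    n_cell_types = as.integer(n_cell_types),
    cell_effect_scale = cell_effect_scale,
    n_plates = as.integer(n_plates),
    noise_sd_mediator = noise_sd_mediator,
    noise_sd_outcome = noise_sd_outcome,
    exposure_covariate_cor = exposure_covariate_cor,
    item_missing_rate = item_missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic cohort: phenotypes and stress-item responses
#'
#' Draws a latent standardized stress exposure, covariates correlated with
#' it at `exposure_covariate_cor` (age, education, smoking), uncorrelated
#' design variables (sex, fasting status, medication flags, measurement
#' year, 10 synthetic ancestry PCs), and item-level responses for the
#' twelve stress measures of [stress_battery()].  Item responses are
#' integers in 0..3 drawn from a binomial whose success probability
#' increases with the participant's latent stress, so the derived
#' cumulative score is a continuous, noisy proxy of the latent exposure.
#' A small fraction of item responses is set missing to exercise the
#' measure-completeness rule.
#'
#' @param config a [sim_config()].
#' @return list with elements `phenotype` (one row per participant; the
#'   column `latent_stress` is the latent exposure the items were generated
#'   from) and `stress_items` (long table: `participant`, `domain`,
#'   `measure`, `item`, `response`).
#' @examples
#' cohort <- sim_cohort(sim_config(n_participants = 30, seed = 3))
#' head(cohort$stress_items)
#' @export
sim_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "`config` must be a sim_config",
          "medewas_config_error")
  n <- config$n_participants
  rho <- config$exposure_covariate_cor
  .assert(abs(rho) < 1, "`exposure_covariate_cor` must lie in (-1, 1)",
          "medewas_config_error")
  set.seed(.child_seed(config$seed, 1L))

  x <- stats::rnorm(n)
  mix_with_x <- function(z) rho * x + sqrt(1 - rho^2) * z

  age <- 70.4 + 9.5 * mix_with_x(stats::rnorm(n))
  sex <- factor(ifelse(stats::runif(n) < 0.59, "female", "male"),
                levels = c("female", "male"))
  # ordinal covariates via thresholded latents correlated with exposure;
  # higher stress shifts toward lower education and current smoking
  edu_lat <- mix_with_x(-stats::rnorm(n))
  education <- cut(stats::pnorm(-edu_lat), c(0, 0.13, 0.74, 1),
                   labels = c("no_degree", "hs_degree", "college"),
                   include.lowest = TRUE)
  smoke_lat <- mix_with_x(stats::rnorm(n))
  smoking <- cut(stats::pnorm(smoke_lat), c(0, 0.45, 0.88, 1),
                 labels = c("never", "former", "current"),
                 include.lowest = TRUE)
  fasting <- stats::runif(n) < 0.5
  med_antihypertensive <- stats::runif(n) < 0.58
  med_statin <- stats::runif(n) < 0.50
  med_diabetes <- stats::runif(n) < 0.21
  stress_year <- factor(sample(c(2010L, 2012L), n, replace = TRUE))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  phenotype <- data.frame(
    participant = sprintf("P%05d", seq_len(n)),
    latent_stress = x,
    age = age, sex = sex, education = education, smoking = smoking,
    fasting = fasting,
    med_antihypertensive = med_antihypertensive,
    med_statin = med_statin, med_diabetes = med_diabetes,
    stress_year = stress_year,
    stringsAsFactors = FALSE
  )
  phenotype <- cbind(phenotype, as.data.frame(pcs))

  battery <- stress_battery()
  item_rows <- vector("list", nrow(battery))
  loading <- 0.55
  for (m in seq_len(nrow(battery))) {
    k <- battery$n_items[m]
    latent_m <- loading * x + sqrt(1 - loading^2) * stats::rnorm(n)
    resp <- matrix(stats::rbinom(n * k, size = 3L,
                                 prob = stats::plogis(latent_m - 0.8)),
                   n, k)
    if (config$item_missing_rate > 0) {
      miss <- matrix(stats::runif(n * k) < config$item_missing_rate, n, k)
      resp[miss] <- NA_integer_
    }
    item_rows[[m]] <- data.frame(
      participant = rep(phenotype$participant, k),
      domain = battery$domain[m],
      measure = battery$measure[m],
      item = rep(seq_len(k), each = n),
      response = as.integer(resp),
      stringsAsFactors = FALSE
    )
  }
  stress_items <- do.call(rbind, item_rows)
  rownames(stress_items) <- NULL
  list(phenotype = phenotype, stress_items = stress_items)
}

#' Generate synthetic methylation mediators with a known truth table
#'
#' Each mediator is assigned a composite-null category by a multinomial
#' draw from `config$null_mix`.  The latent signal is
#' \deqn{M_j = 0.5 + \alpha_j X + \gamma_j^T c + plate_j + \epsilon_j}
#' where `c` are centered cell-type proportions, `plate` a per-plate offset,
#' and the residuals \eqn{\epsilon} are block-exchangeable with correlation
#' `block_rho` within blocks of `block_size` consecutive CpGs.  Values are
#' clipped to `[0.001, 0.999]`; the realized clip rate is attached as the
#' attribute `clip_rate` of the returned matrix.
#'
#' @param config a [sim_config()].
#' @param exposure numeric vector of length `n_participants` (the exposure
#'   used on the \eqn{\alpha} path).
#' @return list with elements `beta` (participants x CpGs matrix), `cells`
#'   (participants x cell types, rows summing to 1), `plate` (factor),
#'   `position_row`, `position_col` (factors), and `truth` (data frame:
#'   `mediator`, `null_category` in H00/H10/H01/H11, `true_alpha`,
#'   `true_beta`, `true_mediation_effect`).
#' @export
sim_methylation <- function(config, exposure) {
  .assert(inherits(config, "sim_config"), "`config` must be a sim_config",
          "medewas_config_error")
  n <- config$n_participants
  .assert(length(exposure) == n,
          sprintf("`exposure` must have length %d (got %d)",
                  n, length(exposure)),
          "medewas_dimension_error")
  J <- config$n_mediators
  set.seed(.child_seed(config$seed, 2L))

  categories <- c("H00", "H10", "H01", "H11")
  null_category <- sample(categories, J, replace = TRUE,
                          prob = config$null_mix)
  true_alpha <- ifelse(null_category %in% c("H10", "H11"),
                       config$alpha_effect, 0)
  true_beta <- ifelse(null_category %in% c("H01", "H11"),
                      config$beta_effect, 0)
  ids <- sprintf("cg%08d", seq_len(J))
  truth <- data.frame(
    mediator = ids, null_category = null_category,
    true_alpha = true_alpha, true_beta = true_beta,
    true_mediation_effect = true_alpha * true_beta,
    stringsAsFactors = FALSE
  )

  # cell-type proportions: Dirichlet rows with a granulocyte-heavy profile
  K <- config$n_cell_types
  cell_names <- c("Gran", "CD4T", "CD8T", "Bcell", "Mono", "NK",
                  paste0("Cell", 7:max(7, K)))[seq_len(K)]
  shapes <- c(12, 5, 3, 2, 2, 1.5, rep(1, max(0, K - 6)))[seq_len(K)]
  cells <- matrix(stats::rgamma(n * K, shape = rep(shapes, each = n)),
                  n, K, dimnames = list(NULL, cell_names))
  cells <- cells / rowSums(cells)

  plate <- factor(sample(seq_len(config$n_plates), n, replace = TRUE),
                  levels = seq_len(config$n_plates),
                  labels = paste0("plate", seq_len(config$n_plates)))
  position_row <- factor(sample(LETTERS[1:8], n, replace = TRUE))
  position_col <- factor(sample(1:12, n, replace = TRUE))

  # nuisance signal: per-CpG linear coefficients on centered cell
  # proportions (dropping one type to avoid the sum-to-one collinearity)
  # and a per-plate offset; both removable by pre-adjustment
  cells_c <- scale(cells[, -K, drop = FALSE], center = TRUE, scale = FALSE)
  gamma <- matrix(stats::rnorm((K - 1) * J, sd = config$cell_effect_scale),
                  K - 1, J)
  plate_eff <- matrix(stats::rnorm(config$n_plates * J,
                                   sd = config$cell_effect_scale),
                      config$n_plates, J)

  # block-exchangeable residuals: shared block factor + idiosyncratic noise
  rho <- config$block_rho
  n_blocks <- ceiling(J / config$block_size)
  block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(J)]
  f <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  eps <- sqrt(rho) * f[, block_of, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * J), n, J)
  eps <- eps * config$noise_sd_mediator

  latent <- 0.5 + outer(as.numeric(exposure), true_alpha) +
    cells_c %*% gamma + plate_eff[as.integer(plate), , drop = FALSE] + eps
  clipped <- latent < 0.001 | latent > 0.999
  beta_mat <- pmin(pmax(latent, 0.001), 0.999)
  dimnames(beta_mat) <- list(sprintf("P%05d", seq_len(n)), ids)
  attr(beta_mat, "clip_rate") <- mean(clipped)

  list(beta = beta_mat, cells = cells, plate = plate,
       position_row = position_row, position_col = position_col,
       truth = truth)
}

#' Generate the synthetic outcome from exposure, mediators, and truth
#'
#' \deqn{Y = \theta X + \sum_j \beta_j M_j + covariate terms + \epsilon}
#' with \eqn{\theta} = `direct_effect`, \eqn{\beta_j} from the truth table,
#' and Gaussian noise with SD `noise_sd_outcome`.  When a phenotype table
#' is supplied, small fixed age and smoking contributions are added so the
#' covariate adjustment in downstream models matters.
#'
#' @param config a [sim_config()].
#' @param exposure numeric exposure vector.
#' @param methylation mediator matrix (participants x CpGs), e.g.
#'   `sim_methylation(...)$beta`.
#' @param truth truth table aligned to the columns of `methylation`.
#' @param phenotype optional phenotype table from [sim_cohort()].
#' @return numeric outcome vector.
#' @export
sim_outcome <- function(config, exposure, methylation, truth,
                        phenotype = NULL) {
  .assert(inherits(config, "sim_config"), "`config` must be a sim_config",
          "medewas_config_error")
  n <- length(exposure)
  .assert(nrow(methylation) == n,
          "`methylation` rows must match `exposure` length",
          "medewas_dimension_error")
  .assert(nrow(truth) == ncol(methylation),
          "`truth` rows must match `methylation` columns",
          "medewas_dimension_error")
  .assert(all(truth$mediator == colnames(methylation)),
          "`truth` mediator ids must align with `methylation` columns",
          "medewas_dimension_error")
  set.seed(.child_seed(config$seed, 3L))

  y <- config$direct_effect * as.numeric(exposure) +
    as.numeric(methylation %*% truth$true_beta)
  if (!is.null(phenotype)) {
    .assert(nrow(phenotype) == n,
            "`phenotype` rows must match `exposure` length",
            "medewas_dimension_error")
    y <- y + 0.02 * (phenotype$age - 70) +
      0.3 * (phenotype$smoking == "current")
  }
  y + stats::rnorm(n, sd = config$noise_sd_outcome)
}

#' Generate a synthetic CpG annotation table
#'
#' Produces a BED-like annotation (chromosome, 1-based position, proximal
#' gene, signed distance to the nearest TSS with upstream negative,
#' absolute distance to the nearest CpG island, enhancer/DHS flags, and an
#' eQTM flag).  True mediators (category H11 in the truth table) are given
#' higher odds of carrying the enhancer and eQTM flags, emulating the
#' functional enrichment the analysis is meant to detect.  The table is
#' synthetic: it carries no real genome coordinates.
#'
#' @param truth truth table from [sim_methylation()].
#' @param seed integer seed.
#' @param eqtm_rate background probability that a CpG is an eQTM.
#' @param enhancer_rate background probability of the enhancer flag.
#' @param eqtm_or,enhancer_or odds multipliers applied to H11 mediators.
#' @return annotation data frame, one row per mediator.
#' @export
sim_annotation <- function(truth, seed = 1L, eqtm_rate = 0.046,
                           enhancer_rate = 0.12, eqtm_or = 8,
                           enhancer_or = 5) {
  J <- nrow(truth)
  set.seed(.child_seed(seed, 4L))
  h11 <- truth$null_category == "H11"
  boost <- function(base_rate, or) {
    odds <- base_rate / (1 - base_rate)
    ifelse(h11, (odds * or) / (1 + odds * or), base_rate)
  }
  # signed TSS distance: negative = upstream; mixture so a realistic
  # fraction of sites lands in the promoter window (-1500, 0]
  dist_tss <- ifelse(stats::runif(J) < 0.25,
                     -stats::runif(J, 0, 1500),
                     round(stats::rnorm(J, 0, 20000)))
  dist_cgi <- ifelse(stats::runif(J) < 0.3, 0,
                     round(abs(stats::rnorm(J, 0, 3000))))
  data.frame(
    mediator = truth$mediator,
    chrom = paste0("chr", sample(1:22, J, replace = TRUE)),
    position = sample.int(2e8, J, replace = TRUE),
    gene = sprintf("GENE%04d", sample.int(5000, J, replace = TRUE)),
    dist_tss = round(dist_tss),
    dist_cgi = dist_cgi,
    enhancer = stats::runif(J) < boost(enhancer_rate, enhancer_or),
    dhs = stats::runif(J) < 0.2,
    eqtm = stats::runif(J) < boost(eqtm_rate, eqtm_or),
    stringsAsFactors = FALSE
  )
}

# Exposure used to generate methylation and outcome: the scored stress
# construct itself (fully prorated, z-standardized over all participants).
# Tying the generative exposure to the scored construct keeps the truth
# table's alpha equal to the coefficient the analysis model estimates;
# driving generation from the latent factor instead would add exposure
# measurement error, whose residual confounding masquerades as mediation.
#' @keywords internal
#' @noRd
.generative_exposure <- function(stress_items, battery = stress_battery()) {
  participants <- sort(unique(stress_items$participant))
  raw <- matrix(NA_real_, length(participants), nrow(battery),
                dimnames = list(participants, battery$measure))
  for (m in seq_len(nrow(battery))) {
    rows <- stress_items[stress_items$measure == battery$measure[m], ]
    k <- battery$n_items[m]
    wide <- matrix(NA_real_, length(participants), k)
    wide[cbind(match(rows$participant, participants), rows$item)] <-
      rows$response
    raw[, m] <- score_measure(wide, n_items = k,
                              completeness_threshold = .Machine$double.eps)
  }
  # a participant with zero answered items on a measure gets that
  # measure's mean (vanishingly rare at realistic missingness)
  na_idx <- which(is.na(raw), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    raw[na_idx] <- colMeans(raw, na.rm = TRUE)[na_idx[, 2]]
  }
  measure_z <- apply(raw, 2, z_standardize)
  domains <- unique(battery$domain)
  domain_z <- sapply(domains, function(d) {
    cols <- battery$measure[battery$domain == d]
    aggregate_domain(measure_z[, cols, drop = FALSE])
  })
  stats::setNames(cumulative_score(domain_z, n_domains = length(domains)),
                  participants)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper bundling [sim_cohort()], [sim_methylation()],
#' [sim_outcome()], and [sim_annotation()].  The exposure driving the
#' methylation and outcome models is the scored cumulative-stress
#' construct derived from the generated items (prorated for everyone and
#' standardized over the full cohort), so the truth table's `true_alpha`
#' is the coefficient the analysis models estimate.
#'
#' @param config a [sim_config()].
#' @return list with `phenotype`, `stress_items`, `exposure` (the
#'   generative cumulative score, one value per participant),
#'   `methylation` (the list returned by [sim_methylation()]), `outcome`,
#'   and `annotation`.
#' @export
sim_study <- function(config) {
  cohort <- sim_cohort(config)
  exposure <- .generative_exposure(cohort$stress_items)
  exposure <- exposure[cohort$phenotype$participant]
  meth <- sim_methylation(config, exposure)
  y <- sim_outcome(config, exposure, meth$beta, meth$truth,
                   cohort$phenotype)
  annot <- sim_annotation(meth$truth, seed = config$seed)
  list(phenotype = cohort$phenotype, stress_items = cohort$stress_items,
       exposure = unname(exposure), methylation = meth, outcome = y,
       annotation = annot)
}

#' Write a synthetic study to delimited text files
#'
#' Writes phenotype, stress-item, methylation, cell-proportion, batch,
#' truth, annotation, and outcome tables as TSV, plus a sidecar
#' `config.tsv` echoing all generator parameters.
#'
#' @param study list from [sim_study()].
#' @param config the [sim_config()] used to generate it.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(study$phenotype, p("phenotype.tsv"))
  write_tsv(study$stress_items, p("stress_items.tsv"))
  meth <- study$methylation
  beta_df <- data.frame(participant = rownames(meth$beta),
                        meth$beta, check.names = FALSE)
  write_tsv(beta_df, p("methylation.tsv"))
  write_tsv(data.frame(participant = rownames(meth$beta), meth$cells,
                       plate = meth$plate,
                       position_row = meth$position_row,
                       position_col = meth$position_col,
                       check.names = FALSE),
            p("cells_batch.tsv"))
  write_tsv(meth$truth, p("truth.tsv"))
  write_tsv(study$annotation, p("annotation.tsv"))
  write_tsv(data.frame(participant = rownames(meth$beta),
                       outcome = study$outcome),
            p("outcome.tsv"))
  cfg <- config
  cfg$null_mix <- paste(cfg$null_mix, collapse = ",")
  write_tsv(data.frame(parameter = names(cfg),
                       value = vapply(cfg, function(v)
                         paste(format(v), collapse = ","), character(1))),
            p("config.tsv"))
  invisible(dir)
}
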