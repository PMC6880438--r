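#' Run a complete low-coverage imputation accuracy experiment
#'
#' Generates (or reuses) the default synthetic panel, draws held-out mosaic
#' targets, simulates pileups at the requested coverage, runs the full
#' two-stage imputation pipeline, and evaluates per-sample and per-site
#' dosage r2 with MAF-bucket stratification.
#'
#' @param config A [sim_config()]; its `seed` drives the panel.
#' @param n_targets Number of held-out targets.
#' @param coverage Mean sequencing coverage.
#' @param seed Seed for targets and reads (panel uses `config$seed`).
#' @param params,panel_size,base_error Pipeline parameters.
#' @param panel,targets Optionally reuse a previously generated panel /
#'   target set instead of regenerating them.
#' @return List with `panel`, `targets`, `pileups`, `dosages`, `per_sample`,
#'   `per_site`, `buckets`, `mean_r2`.
#' @export
run_imputation_experiment <- function(config = sim_config(), n_targets = 20L,
                                      coverage = 0.5, seed = 1L,
                                      params = hmm_params(), panel_size = 250L,
                                      base_error = 0.005,
                                      panel = NULL, targets = NULL) {
  if (is.null(panel)) panel <- generate_panel(config)$panel
  if (is.null(targets)) {
    tg <- generate_targets(panel, n_targets, n_relatives = 0L, seed = seed + 1L)
    targets <- tg$truth; panel <- tg$panel
  }
  pl <- simulate_pileups(targets, coverage, base_error = base_error,
                         seed = seed + 2L)
  dm <- impute_cohort(pl, panel, params = params, panel_size = panel_size,
                      relative_of = targets$relative_of)
  per_sample <- dosage_r2(dm, targets, "per_sample")
  per_site <- dosage_r2(dm, targets, "per_site")
  buckets <- maf_buckets(per_site, panel$sites$maf)
  list(panel = panel, targets = targets, pileups = pl, dosages = dm,
       per_sample = per_sample, per_site = per_site, buckets = buckets,
       mean_r2 = mean(per_sample$r2, na.rm = TRUE))
}

#' Polygenic-score concordance experiment
#'
#' Imputes a held-out cohort at the given coverage, computes raw polygenic
#' scores from the imputed dosages and from the true genotypes, and
#' summarizes their concordance (r2, mean- and variance-equality tests).
#'
#' @param config A [sim_config()].
#' @param n_targets Cohort size (default 50).
#' @param coverage Mean coverage (default 1.2, a typical lcWGS run).
#' @param n_score_variants Entries in the synthetic score (default 1000).
#' @param seed Seed for targets, reads and score.
#' @param params,panel_size Pipeline parameters.
#' @param panel Optional pre-generated panel.
#' @return List with `concordance`, `gps_lc`, `gps_truth`, `score`,
#'   `dosages`, `targets`, `panel`.
#' @export
run_concordance_experiment <- function(config = sim_config(), n_targets = 50L,
                                       coverage = 1.2, n_score_variants = 1000L,
                                       seed = 1L, params = hmm_params(),
                                       panel_size = 250L, panel = NULL) {
  if (is.null(panel)) panel <- generate_panel(config)$panel
  tg <- generate_targets(panel, n_targets, n_relatives = 0L, seed = seed + 11L)
  targets <- tg$truth; panel <- tg$panel
  pl <- simulate_pileups(targets, coverage, seed = seed + 12L)
  dm <- impute_cohort(pl, panel, params = params, panel_size = panel_size,
                      relative_of = targets$relative_of)
  score <- generate_score(panel, n_score_variants, seed = seed + 13L)
  gps_lc <- compute_gps(dm, score)
  gps_truth <- compute_gps(targets, score)
  list(concordance = gps_concordance(gps_lc, gps_truth),
       gps_lc = gps_lc, gps_truth = gps_truth, score = score,
       dosages = dm, targets = targets, panel = panel)
}

#' Cohort phenotype-association experiment
#'
#' Generates a large cohort of mosaic genotypes on a compact panel, computes
#' raw polygenic scores, draws binary phenotypes under the logistic
#' liability model with a planted odds ratio per SD, normalizes the scores
#' as PC-residual z-scores, and refits the association.
#'
#' @param n_cohort Cohort size (default 10000).
#' @param true_or_per_sd Planted odds ratio per SD (default 1.6).
#' @param prevalence Phenotype prevalence (default 0.1).
#' @param seed Seed.
#' @param config Panel configuration; the default uses a compact 800-site
#'   panel since association depends on scores, not site count.
#' @param n_score_variants Score entries (default 300).
#' @param covariates Covariate names passed to [associate_gps()].
#' @return List with `association`, `phenotypes`, `normalized`, `raw`,
#'   `score`, `panel`.
#' @export
run_cohort_experiment <- function(n_cohort = 10000L, true_or_per_sd = 1.6,
                                  prevalence = 0.1, seed = 1L,
                                  config = sim_config(n_sites = 900L,
                                                      n_panel_samples = 100L,
                                                      seed = 42L),
                                  n_score_variants = 300L,
                                  covariates = c("age", "sex")) {
  panel <- generate_panel(config)$panel
  tg <- generate_targets(panel, n_cohort, n_relatives = 0L, seed = seed + 21L)
  cohort <- tg$truth
  score <- generate_score(panel, n_score_variants, seed = seed + 22L)
  raw <- compute_gps(cohort, score)
  phen <- generate_phenotypes(raw, true_or_per_sd, prevalence, seed = seed + 23L)
  pcs <- pc_project(cohort, panel, n_pcs = 10L)
  z <- normalize_gps(raw, pcs$coords)
  assoc <- associate_gps(z, phen, covariates = covariates)
  list(association = assoc, phenotypes = phen, normalized = z, raw = raw,
       score = score, panel = panel)
}
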