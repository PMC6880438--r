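#' Parameters of the haplotype-copying imputation HMM
#'
#' The hidden state is an ordered pair of reference haplotypes. Over an
#' interval of genetic length `d` cM each haplotype independently switches,
#' with probability `tau = 1 - exp(-scale * rho * d / K)`, to a uniformly
#' random template among the K panel haplotypes. Emissions mix the genotype
#' weights with a per-allele copy fidelity: a copied allele matches its
#' template with probability `1 - lambda`.
#'
#' @param rho Switch intensity per centiMorgan. `NULL` (default) uses the
#'   population-scaled choice `rho = K` at run time, so the effective
#'   per-haplotype switch rate is `scale * 1.0` per cM.
#' @param lambda Allele miscopy probability, in (0, 0.5).
#' @param scale Model scale multiplier on the switch intensity (default 2).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(rho = NULL, lambda = 1e-3, scale = 2) {
  if (!is.null(rho)) stop_if_not_scalar(rho, "rho", lower = 0, open_lower = TRUE)
  stop_if_not_scalar(lambda, "lambda", lower = 0, upper = 0.5,
                     open_lower = TRUE, open_upper = TRUE)
  stop_if_not_scalar(scale, "scale", lower = 0, open_lower = TRUE)
  structure(list(rho = rho, lambda = lambda, scale = scale),
            class = "hmm_params")
}

# per-interval switch probability for K panel haplotypes
switch_probs <- function(distances_cm, params, K) {
  rho <- params$rho %||% K
  1 - exp(-params$scale * rho * distances_cm / K)
}

#' Exact diploid forward-backward over a haplotype panel
#'
#' Computes, for every site, the exact posterior distribution of the
#' genotype given all emissions, under the diploid Li-Stephens
#' haplotype-copying model (ordered-pair state space of size K^2). Scaled
#' arithmetic is used throughout so there is no underflow at realistic site
#' counts.
#'
#' @param emissions n_sites x 3 matrix of nonnegative genotype weights
#'   (genotype likelihoods, posterior triplets, or near-delta array calls);
#'   each row must contain at least one positive entry.
#' @param haplotypes K x n_sites binary matrix of panel haplotypes.
#' @param genetic_map Numeric vector of `n_sites - 1` inter-site genetic
#'   distances in centiMorgans.
#' @param params An [hmm_params()] object.
#' @return List with `posterior` (n_sites x 3, rows sum to 1) and `dosage`
#'   (`P(g=1) + 2 P(g=2)`).
#' @export
forward_backward <- function(emissions, haplotypes, genetic_map,
                             params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  emissions <- as.matrix(emissions)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  K <- nrow(haplotypes); M <- ncol(haplotypes)
  if (M < 1 || K < 1) stop("need at least one haplotype and one site")
  if (nrow(emissions) != M || ncol(emissions) != 3L)
    stop("`emissions` must be n_sites x 3")
  if (M > 1 && length(genetic_map) != M - 1L)
    stop("`genetic_map` must have n_sites - 1 interval distances")
  if (any(genetic_map < 0)) stop("genetic distances must be >= 0")
  tau <- if (M > 1) switch_probs(genetic_map, params, K) else numeric(0)
  post <- .fb_diploid_cpp(haplotypes, emissions, tau, params$lambda)
  colnames(post) <- c("g0", "g1", "g2")
  list(posterior = post, dosage = as.numeric(post[, 2] + 2 * post[, 3]))
}

#' Stage-1 reference-aware genotype calling at covered sites
#'
#' Runs the forward-backward pass over the subsequence of sites covered by
#' at least one read, with the sample's genotype likelihoods as emissions,
#' against the custom reference panel's haplotypes. A single pass is made
#' (no phasing iterations). Output is restricted to the covered sites.
#'
#' @param gl_sample One element of a `gl_set` (`gl$samples[[i]]`).
#' @param custom A `custom_panel` from [select_custom_panel()].
#' @param panel The `haplotype_panel` the custom panel indexes into.
#' @param params [hmm_params()].
#' @return List with `sample_id`, `covered` (site indices), `posterior`
#'   (length(covered) x 3) and `dosage` at covered sites.
#' @export
impute_stage1 <- function(gl_sample, custom, panel, params = hmm_params()) {
  stopifnot(inherits(custom, "custom_panel"), inherits(panel, "haplotype_panel"))
  if (length(custom$selected) == 0L) stop("custom panel is empty")
  covered <- gl_sample$covered
  if (length(covered) == 0L)
    stop(sprintf("sample %s has zero covered sites", gl_sample$sample_id))
  rows <- hap_rows(match(custom$selected, panel$sample_ids))
  haps <- panel$haplotypes[rows, covered, drop = FALSE]
  cm <- panel$cum_cm[covered]
  fb <- forward_backward(gl_sample$lik, haps,
                         if (length(covered) > 1) diff(cm) else numeric(0),
                         params)
  list(sample_id = gl_sample$sample_id, covered = covered,
       posterior = fb$posterior, dosage = fb$dosage)
}

#' Stage-2 imputation of dosages at all panel sites
#'
#' Runs the forward-backward pass over every panel site against the full
#' panel (optionally minus excluded samples, e.g. the target's relatives),
#' using the stage-1 posterior triplets as emissions at covered sites and
#' uniform emissions elsewhere.
#'
#' @param stage1 Output of [impute_stage1()].
#' @param panel A `haplotype_panel`.
#' @param params [hmm_params()].
#' @param exclude Panel sample ids to leave out of the copying panel.
#' @return List with `sample_id`, `dosage` (all sites), `posterior`
#'   (n_sites x 3) and `covered`.
#' @export
impute_stage2 <- function(stage1, panel, params = hmm_params(),
                          exclude = character(0)) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(stage1$covered) == 0L) stop("stage-1 output is empty")
  m <- nrow(panel$sites)
  emis <- matrix(1, m, 3)
  emis[stage1$covered, ] <- stage1$posterior
  keep <- setdiff(panel$sample_ids, exclude)
  if (length(keep) == 0L) stop("no panel samples left after exclusions")
  rows <- hap_rows(match(keep, panel$sample_ids))
  fb <- forward_backward(emis, panel$haplotypes[rows, , drop = FALSE],
                         panel$genetic_map, params)
  list(sample_id = stage1$sample_id, dosage = fb$dosage,
       posterior = fb$posterior, covered = stage1$covered)
}

#' Impute a whole cohort of low-coverage samples
#'
#' The full two-stage pipeline per sample: genotype likelihoods -> IBS
#' custom-panel selection (dosage-based IBS at the sample's densest-covered
#' decile of sites) -> stage-1 reference-aware calling at covered sites ->
#' stage-2 imputation to all panel sites against the full panel. Relatives
#' recorded in the panel pedigree (or supplied via `relative_of`) are
#' excluded from both the custom panel and the stage-2 copying panel.
#'
#' @param pileups A `pileup_set` for the cohort.
#' @param panel A `haplotype_panel`.
#' @param params [hmm_params()].
#' @param panel_size Custom panel size (default 250).
#' @param error_rate Genotype-likelihood error rate.
#' @param relative_of Named list mapping target sample id -> panel sample
#'   ids to exclude (defaults to the panel pedigree plus any `relative_of`
#'   attribute carried by the pileups' truth source).
#' @param keep_posterior Keep per-site posterior triplets (memory heavy for
#'   large cohorts).
#' @return A `dosage_matrix`: list with `dosage` (samples x sites matrix),
#'   `sites`, `sample_ids`, `covered` (list of covered-site indices),
#'   optional `posterior` array, and `provenance`.
#' @export
impute_cohort <- function(pileups, panel, params = hmm_params(),
                          panel_size = 250L, error_rate = NULL,
                          relative_of = NULL, keep_posterior = FALSE) {
  stopifnot(inherits(pileups, "pileup_set"), inherits(panel, "haplotype_panel"))
  err <- error_rate %||% (if (is.finite(pileups$base_error %||% NA_real_))
    pileups$base_error else 0.005)
  gls <- compute_gl(pileups, error_rate = err)
  m <- nrow(panel$sites)
  n <- length(pileups$sample_ids)
  D <- matrix(NA_real_, n, m, dimnames = list(pileups$sample_ids, NULL))
  post <- if (keep_posterior) array(NA_real_, c(n, m, 3)) else NULL
  covered_list <- vector("list", n)
  rel_lookup <- function(id) {
    ped <- names(Filter(function(v) id %in% v, panel$pedigree))
    unique(c(ped, relative_of[[id]] %||% character(0)))
  }
  for (i in seq_len(n)) {
    gs <- gls$samples[[i]]
    id <- gs$sample_id
    depth <- pileups$n_ref[i, ] + pileups$n_alt[i, ]
    dos0 <- gl_dosage(gs, m)
    comp <- densest_decile(depth)
    excl <- rel_lookup(id)
    sim <- ibs_similarity(dos0, panel, comp)
    custom <- select_custom_panel(sim, panel, id, panel_size, exclude = excl)
    s1 <- impute_stage1(gs, custom, panel, params)
    s2 <- impute_stage2(s1, panel, params, exclude = c(id, excl))
    D[i, ] <- s2$dosage
    if (keep_posterior) post[i, , ] <- s2$posterior
    covered_list[[i]] <- gs$covered
  }
  structure(list(dosage = D, sites = panel$sites,
                 sample_ids = pileups$sample_ids, covered = covered_list,
                 posterior = post,
                 provenance = list(stage = "two-stage lcWGS",
                                   panel_size = panel_size,
                                   params = unclass(params),
                                   error_rate = err,
                                   nominal_coverage = pileups$nominal_coverage)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d sites (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              x$provenance$stage %||% "unknown provenance"))
  invisible(x)
}

#' Single-pass imputation variant
#'
#' One forward-backward run over all panel sites with genotype-likelihood
#' emissions at covered sites and flat emissions elsewhere, against the full
#' panel. Used as an internal-consistency comparator for the two-stage
#' pipeline.
#'
#' @inheritParams impute_cohort
#' @return A `dosage_matrix`.
#' @export
impute_single_pass <- function(pileups, panel, params = hmm_params(),
                               error_rate = NULL, relative_of = NULL) {
  stopifnot(inherits(pileups, "pileup_set"), inherits(panel, "haplotype_panel"))
  err <- error_rate %||% (if (is.finite(pileups$base_error %||% NA_real_))
    pileups$base_error else 0.005)
  gls <- compute_gl(pileups, error_rate = err)
  m <- nrow(panel$sites)
  n <- length(pileups$sample_ids)
  D <- matrix(NA_real_, n, m, dimnames = list(pileups$sample_ids, NULL))
  for (i in seq_len(n)) {
    gs <- gls$samples[[i]]
    emis <- matrix(1, m, 3)
    emis[gs$covered, ] <- gs$lik
    excl <- c(gs$sample_id, relative_of[[gs$sample_id]] %||% character(0),
              names(Filter(function(v) gs$sample_id %in% v, panel$pedigree)))
    keep <- setdiff(panel$sample_ids, excl)
    rows <- hap_rows(match(keep, panel$sample_ids))
    fb <- forward_backward(emis, panel$haplotypes[rows, , drop = FALSE],
                           panel$genetic_map, params)
    D[i, ] <- fb$dosage
  }
  structure(list(dosage = D, sites = panel$sites,
                 sample_ids = pileups$sample_ids,
                 covered = lapply(gls$samples, `[[`, "covered"),
                 posterior = NULL,
                 provenance = list(stage = "single-pass lcWGS",
                                   params = unclass(params), error_rate = err)),
            class = "dosage_matrix")
}
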