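#' Simulation configuration for the synthetic reference panel
#'
#' Bundles every parameter of the founder-mosaic panel generator. The
#' defaults describe the package's reference study conditions: five
#' populations (named after continental super-population labels), 250 phased
#' panel samples, roughly 4,000 biallelic sites spread over a 10 Mb region
#' with a ~10 cM genetic map, and a site-frequency spectrum with substantial
#' mass in the common (>5%), low-frequency (1-5%) and rare (<1%) minor
#' allele frequency buckets.
#'
#' @param n_founders Founder haplotypes per population. Founder alleles are
#'   drawn i.i.d. per site from population-specific frequencies; all panel
#'   haplotypes are recombinant mosaics of their population's founders.
#' @param n_panel_samples Diploid samples in the reference panel (split as
#'   evenly as possible across populations).
#' @param n_target_samples Default number of held-out target samples drawn by
#'   [generate_targets()].
#' @param n_sites Number of candidate sites drawn before the allele-frequency
#'   filter; sites monomorphic in the panel or below `maf_filter_threshold`
#'   in every population are dropped, so the emitted panel is somewhat
#'   smaller.
#' @param region_length_bp Length of the simulated region in base pairs.
#' @param cm_per_mb Genetic map density (centiMorgans per megabase).
#' @param mosaic_switch_rate Haplotype-copying switch intensity per
#'   centiMorgan used when building mosaic haplotypes.
#' @param mutation_miscopy_rate Per-site probability that a copied allele is
#'   flipped (mutation/miscopy noise).
#' @param population_spec List with `labels` (character vector of population
#'   names) and `drift` (Balding-Nichols F_ST-like divergence between the
#'   shared ancestral frequency and each population's frequency).
#' @param maf_filter_threshold A site is retained if its alternate-allele
#'   frequency is at least this value in at least one population (0 disables
#'   the frequency filter; monomorphic sites are always dropped).
#' @param seed Integer seed; a fixed config + seed reproduces the panel
#'   byte-identically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 50L,
                       n_panel_samples = 250L,
                       n_target_samples = 20L,
                       n_sites = 4500L,
                       region_length_bp = 1e7,
                       cm_per_mb = 1.0,
                       mosaic_switch_rate = 1.0,
                       mutation_miscopy_rate = 1e-3,
                       population_spec = list(
                         labels = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                         drift = 0.05),
                       maf_filter_threshold = 0.01,
                       seed = 1L) {
  for (nm in c("n_founders", "n_panel_samples", "n_target_samples", "n_sites"))
    stop_if_not_scalar(get(nm), nm, lower = 1)
  stop_if_not_scalar(region_length_bp, "region_length_bp", lower = 1000)
  stop_if_not_scalar(cm_per_mb, "cm_per_mb", lower = 0, open_lower = TRUE)
  stop_if_not_scalar(mosaic_switch_rate, "mosaic_switch_rate", lower = 0)
  stop_if_not_scalar(mutation_miscopy_rate, "mutation_miscopy_rate",
                     lower = 0, upper = 1, open_upper = TRUE)
  stop_if_not_scalar(maf_filter_threshold, "maf_filter_threshold",
                     lower = 0, upper = 0.5)
  if (!is.list(population_spec) || is.null(population_spec$labels))
    stop("`population_spec` must be a list with `labels` and `drift`")
  population_spec$drift <- population_spec$drift %||% 0.05
  stop_if_not_scalar(population_spec$drift, "population_spec$drift",
                     lower = 0, upper = 1, open_upper = TRUE)
  cfg <- list(n_founders = as.integer(n_founders),
              n_panel_samples = as.integer(n_panel_samples),
              n_target_samples = as.integer(n_target_samples),
              n_sites = as.integer(n_sites),
              region_length_bp = region_length_bp,
              cm_per_mb = cm_per_mb,
              mosaic_switch_rate = mosaic_switch_rate,
              mutation_miscopy_rate = mutation_miscopy_rate,
              population_spec = population_spec,
              maf_filter_threshold = maf_filter_threshold,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# ancestral alternate-allele frequency spectrum: a mixture placing sites in
# the common, low-frequency and rare MAF buckets
draw_base_freq <- function(n) {
  cls <- sample.int(3L, n, replace = TRUE, prob = c(0.55, 0.27, 0.18))
  p <- numeric(n)
  p[cls == 1L] <- runif(sum(cls == 1L), 0.05, 0.5)
  p[cls == 2L] <- runif(sum(cls == 2L), 0.01, 0.05)
  p[cls == 3L] <- runif(sum(cls == 3L), 0.001, 0.02)
  # random allele orientation so alt is not always minor
  flip <- runif(n) < 0.5
  p[flip] <- 1 - p[flip]
  p
}

# one recombinant mosaic haplotype copied from `pool` (haplotypes x sites)
# cum_cm: cumulative genetic position (length n_sites)
mosaic_haplotype <- function(pool, cum_cm, switch_rate, miscopy_rate) {
  m <- ncol(pool)
  total_cm <- cum_cm[m] - cum_cm[1]
  n_sw <- if (switch_rate > 0 && total_cm > 0) rpois(1L, switch_rate * total_cm) else 0L
  hap <- integer(m)
  if (n_sw == 0L) {
    hap <- pool[sample.int(nrow(pool), 1L), ]
  } else {
    bp <- sort(runif(n_sw, cum_cm[1], cum_cm[m]))
    after <- findInterval(bp, cum_cm)           # switch occurs after this site
    starts <- unique(c(1L, after + 1L))
    starts <- starts[starts <= m]
    ends <- c(starts[-1L] - 1L, m)
    src <- sample.int(nrow(pool), length(starts), replace = TRUE)
    for (k in seq_along(starts))
      hap[starts[k]:ends[k]] <- pool[src[k], starts[k]:ends[k]]
  }
  if (miscopy_rate > 0) {
    nflip <- rbinom(1L, m, miscopy_rate)
    if (nflip > 0L) {
      at <- sample.int(m, nflip)
      hap[at] <- 1L - hap[at]
    }
  }
  hap
}

#' Generate a phased synthetic reference haplotype panel
#'
#' Draws founder haplotypes i.i.d. per site from population-specific allele
#' frequencies (a Balding-Nichols drift model around a shared ancestral
#' frequency), builds each panel haplotype as a recombinant mosaic of its
#' population's founders (switch locations Poisson on the genetic map,
#' copied alleles flipped with the miscopy rate), then applies the
#' allele-frequency site filter: sites whose alternate-allele frequency is
#' below `maf_filter_threshold` in every population, or that are monomorphic
#' across the whole panel, are dropped.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (class `haplotype_panel`: `sites` data frame
#'   with per-population allele frequencies, `haplotypes` binary matrix of
#'   2 x n_samples rows, `sample_ids`, `population_of`, `genetic_map`
#'   per-interval centiMorgan distances, `pedigree`, and the generating
#'   `config`) and `truth` (class `truth_genotypes` for the panel samples).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    pops <- config$population_spec$labels
    npop <- length(pops)
    Fst <- config$population_spec$drift
    m0 <- config$n_sites

    pos <- sort(sample.int(config$region_length_bp, m0))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m0, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    p0 <- draw_base_freq(m0)
    pop_freq <- matrix(0, npop, m0, dimnames = list(pops, NULL))
    if (Fst > 0) {
      a <- p0 * (1 - Fst) / Fst
      b <- (1 - p0) * (1 - Fst) / Fst
      for (k in seq_len(npop)) pop_freq[k, ] <- rbeta(m0, a, b)
    } else {
      for (k in seq_len(npop)) pop_freq[k, ] <- p0
    }

    # genetic map: cumulative cM proportional to physical position
    cum_cm <- pos / 1e6 * config$cm_per_mb
    n_per <- diff(round(seq(0, config$n_panel_samples, length.out = npop + 1)))
    sample_pop <- rep(pops, times = n_per)
    n_samples <- length(sample_pop)
    sample_ids <- sprintf("PNL%04d", seq_len(n_samples))
    names(sample_pop) <- sample_ids

    haps <- matrix(0L, 2L * n_samples, m0)
    for (k in seq_len(npop)) {
      founders <- matrix(
        rbinom(config$n_founders * m0, 1L, rep(pop_freq[k, ], each = config$n_founders)),
        nrow = config$n_founders)
      rows <- hap_rows(which(sample_pop == pops[k]))
      for (r in rows)
        haps[r, ] <- mosaic_haplotype(founders, cum_cm,
                                      config$mosaic_switch_rate,
                                      config$mutation_miscopy_rate)
    }

    # realized per-population frequencies drive the site filter
    af <- matrix(0, npop, m0, dimnames = list(pops, NULL))
    for (k in seq_len(npop)) {
      rows <- hap_rows(which(sample_pop == pops[k]))
      af[k, ] <- colMeans(haps[rows, , drop = FALSE])
    }
    af_global <- colMeans(haps)
    poly <- af_global > 0 & af_global < 1
    freq_ok <- apply(af >= config$maf_filter_threshold, 2L, any)
    keep <- which(poly & freq_ok)
    if (length(keep) == 0L)
      stop("no sites survive the allele-frequency filter (maf_filter_threshold = ",
           config$maf_filter_threshold, ") and monomorphic-site removal")

    sites <- data.frame(chrom = "chrS", pos = pos[keep], ref = ref[keep],
                        alt = alt[keep], stringsAsFactors = FALSE)
    afk <- t(af[, keep, drop = FALSE])
    colnames(afk) <- paste0("af_", pops)
    sites <- cbind(sites, as.data.frame(afk))
    sites$af_global <- af_global[keep]
    sites$maf <- pmin(sites$af_global, 1 - sites$af_global)

    panel <- structure(list(
      sites = sites,
      haplotypes = haps[, keep, drop = FALSE],
      sample_ids = sample_ids,
      population_of = sample_pop,
      genetic_map = diff(cum_cm[keep]),
      cum_cm = cum_cm[keep],
      pedigree = stats::setNames(vector("list", n_samples), sample_ids),
      config = config), class = "haplotype_panel")

    truth <- structure(list(
      sample_ids = sample_ids,
      genotypes = haps_to_genotypes(panel$haplotypes),
      haplotypes = panel$haplotypes,
      sites = sites,
      population_of = sample_pop,
      relative_of = list()), class = "truth_genotypes")
    rownames(truth$genotypes) <- sample_ids

    list(panel = panel, truth = truth)
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples (%d haplotypes), %d sites, %d populations\n",
              length(x$sample_ids), nrow(x$haplotypes), nrow(x$sites),
              length(unique(x$population_of))))
  cat(sprintf("  genetic map: %.2f cM over %.1f Mb\n",
              sum(x$genetic_map), diff(range(x$sites$pos)) / 1e6))
  invisible(x)
}

#' Generate held-out diploid target samples
#'
#' Each target is a recombinant mosaic of the panel haplotypes of one
#' population (same switch/miscopy process as the panel itself). The first
#' `n_relatives` targets are built as first-degree relatives: one haplotype
#' is an exact, unrecombined copy of a designated panel sample's haplotype,
#' and the relationship is recorded in the panel pedigree so that
#' relative-exclusion in custom-panel selection is testable.
#'
#' @param panel A `haplotype_panel`.
#' @param n Number of targets.
#' @param n_relatives How many of the targets share an unrecombined parental
#'   haplotype with a panel sample (must be `<= n`).
#' @param seed Integer seed.
#' @return List with `truth` (class `truth_genotypes`, including phased
#'   haplotypes and the `relative_of` map) and `panel` (the input panel with
#'   its pedigree updated).
#' @export
generate_targets <- function(panel, n, n_relatives = 0L, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$sites) == 0L) stop("panel has no sites")
  stop_if_not_scalar(n, "n", lower = 1)
  stop_if_not_scalar(n_relatives, "n_relatives", lower = 0)
  if (n_relatives > n) stop("`n_relatives` cannot exceed `n`")
  cfg <- panel$config
  with_seed(seed, {
    m <- nrow(panel$sites)
    pops <- unique(panel$population_of)
    ids <- sprintf("TGT%04d", seq_len(n))
    haps <- matrix(0L, 2L * n, m)
    pop_of <- character(n)
    relative_of <- list()

    parents <- if (n_relatives > 0L)
      sample(panel$sample_ids, n_relatives) else character(0)

    for (i in seq_len(n)) {
      if (i <= n_relatives) {
        parent <- parents[i]
        pop <- panel$population_of[[parent]]
        prow <- hap_rows(match(parent, panel$sample_ids))
        pool <- panel$haplotypes[hap_rows(which(panel$population_of == pop)), , drop = FALSE]
        haps[2L * i - 1L, ] <- panel$haplotypes[sample(prow, 1L), ]
        haps[2L * i, ] <- mosaic_haplotype(pool, panel$cum_cm,
                                           cfg$mosaic_switch_rate,
                                           cfg$mutation_miscopy_rate)
        relative_of[[ids[i]]] <- parent
        panel$pedigree[[parent]] <- union(panel$pedigree[[parent]], ids[i])
      } else {
        pop <- pops[((i - 1L) %% length(pops)) + 1L]
        pool <- panel$haplotypes[hap_rows(which(panel$population_of == pop)), , drop = FALSE]
        haps[2L * i - 1L, ] <- mosaic_haplotype(pool, panel$cum_cm,
                                                cfg$mosaic_switch_rate,
                                                cfg$mutation_miscopy_rate)
        haps[2L * i, ] <- mosaic_haplotype(pool, panel$cum_cm,
                                           cfg$mosaic_switch_rate,
                                           cfg$mutation_miscopy_rate)
      }
      pop_of[i] <- pop
    }
    geno <- haps_to_genotypes(haps)
    rownames(geno) <- ids
    truth <- structure(list(
      sample_ids = ids, genotypes = geno, haplotypes = haps,
      sites = panel$sites, population_of = stats::setNames(pop_of, ids),
      relative_of = relative_of), class = "truth_genotypes")
    list(truth = truth, panel = panel)
  })
}

#' Generate a synthetic weighted polygenic score definition
#'
#' Samples `n_variants` panel sites without replacement and assigns centered
#' Gaussian weights scaled by `weight_scale`. Half of the entries use the
#' alternate allele as the effect allele and half the reference allele, so
#' downstream scoring must handle allele orientation. If
#' `confound_populations` names two panel populations, the effect allele of
#' every entry is instead oriented toward the allele that is more frequent
#' in the first population and all weights are positive, planting an
#' ancestry confound (used to exercise principal-component score
#' normalization).
#'
#' @param panel A `haplotype_panel`.
#' @param n_variants Number of score entries (`<=` number of panel sites).
#' @param weight_scale Standard deviation of the weights.
#' @param seed Integer seed.
#' @param confound_populations Optional length-2 character vector of panel
#'   population labels.
#' @return A `score_definition`: data frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `effect_allele` (the allele character), `weight`.
#' @export
generate_score <- function(panel, n_variants, weight_scale = 0.1, seed = 1L,
                           confound_populations = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- nrow(panel$sites)
  if (n_variants > m)
    stop(sprintf("n_variants (%d) exceeds the number of panel sites (%d)",
                 n_variants, m))
  with_seed(seed, {
    idx <- sort(sample.int(m, n_variants))
    s <- panel$sites[idx, , drop = FALSE]
    if (is.null(confound_populations)) {
      w <- rnorm(n_variants) * weight_scale
      is_alt <- sample(rep(c(TRUE, FALSE), length.out = n_variants))
    } else {
      stopifnot(length(confound_populations) == 2L)
      afc <- paste0("af_", confound_populations)
      if (!all(afc %in% names(s))) stop("unknown population in `confound_populations`")
      w <- abs(rnorm(n_variants)) * weight_scale
      is_alt <- s[[afc[1]]] >= s[[afc[2]]]
    }
    out <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                      effect_allele = ifelse(is_alt, s$alt, s$ref),
                      weight = w, stringsAsFactors = FALSE)
    attr(out, "name") <- "synthetic_gps"
    class(out) <- c("score_definition", "data.frame")
    out
  })
}

#' Generate binary phenotypes under a logistic liability model
#'
#' Standardizes the supplied raw polygenic scores, sets the log-odds slope to
#' `log(true_or_per_sd)`, finds the intercept by root-finding so that the
#' expected prevalence matches `prevalence`, and draws Bernoulli phenotypes.
#' Covariates (age, sex by default) are generated independently of the score.
#'
#' @param raw_scores Named numeric vector of per-sample raw scores.
#' @param true_or_per_sd Generating odds ratio per standard deviation of the
#'   score (1.0 means no association).
#' @param prevalence Target expected case fraction, in (0, 1).
#' @param covariate_spec List describing covariates; default simulates
#'   `age ~ N(55, 8)` and `sex ~ Bernoulli(0.5)`.
#' @param seed Integer seed.
#' @return A `phenotype_set`: data frame with `sample_id`, `phenotype`, the
#'   covariates, plus attributes recording the generating parameters.
#' @export
generate_phenotypes <- function(raw_scores, true_or_per_sd, prevalence,
                                covariate_spec = list(age = c(mean = 55, sd = 8),
                                                      sex = 0.5),
                                seed = 1L) {
  if (length(raw_scores) < 2L) stop("need at least 2 samples")
  stop_if_not_scalar(true_or_per_sd, "true_or_per_sd", lower = 0, open_lower = TRUE)
  stop_if_not_scalar(prevalence, "prevalence", lower = 0, upper = 1,
                     open_lower = TRUE, open_upper = TRUE)
  if (sd(raw_scores) == 0) stop("raw scores have zero variance")
  with_seed(seed, {
    z <- as.numeric(scale(raw_scores))
    beta <- log(true_or_per_sd)
    alpha <- uniroot(function(a) mean(plogis(a + beta * z)) - prevalence,
                     interval = c(-80, 80), tol = 1e-10)$root
    y <- rbinom(length(z), 1L, plogis(alpha + beta * z))
    out <- data.frame(sample_id = names(raw_scores) %||%
                        sprintf("S%05d", seq_along(z)),
                      phenotype = y, stringsAsFactors = FALSE)
    for (nm in names(covariate_spec)) {
      spec <- covariate_spec[[nm]]
      out[[nm]] <- if (length(spec) == 2L)
        rnorm(length(z), spec[["mean"]], spec[["sd"]])
      else rbinom(length(z), 1L, spec)
    }
    attr(out, "params") <- list(true_or_per_sd = true_or_per_sd,
                                prevalence = prevalence,
                                alpha = alpha, seed = seed)
    class(out) <- c("phenotype_set", "data.frame")
    out
  })
}
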