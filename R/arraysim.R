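#' Simulate a genotyping-array observation of a cohort
#'
#' Typed sites are sampled with probability proportional to
#' `maf^ascertainment_weight`, emulating the common-variant ascertainment
#' bias of array design (weight 0 gives an unbiased site draw). Typed
#' genotypes are the truth, perturbed: each entry is missing with
#' probability `miss_rate`, and each non-missing entry is replaced by one of
#' the other two genotypes (uniformly) with probability `geno_error`.
#'
#' @param truth A `truth_genotypes`.
#' @param panel The `haplotype_panel` supplying global MAF for the
#'   ascertainment weighting.
#' @param typed_fraction Fraction of panel sites placed on the array.
#' @param miss_rate Per-entry missingness probability, in \[0, 1).
#' @param geno_error Per-entry genotype error probability, in \[0, 1).
#' @param ascertainment_weight Exponent on MAF in the typed-site sampling
#'   weights.
#' @param seed Integer seed.
#' @return An `array_genotypes`: list with `typed` (site indices),
#'   `genotypes` (samples x typed sites, `NA` = missing), `sites` (typed
#'   subset of the site table), per-site `missingness` and per-sample
#'   `call_rate`.
#' @export
simulate_array <- function(truth, panel, typed_fraction = 0.2,
                           miss_rate = 0.01, geno_error = 0.002,
                           ascertainment_weight = 1, seed = 1L) {
  stopifnot(inherits(truth, "truth_genotypes"), inherits(panel, "haplotype_panel"))
  stop_if_not_scalar(typed_fraction, "typed_fraction", lower = 0, upper = 1,
                     open_lower = TRUE)
  stop_if_not_scalar(miss_rate, "miss_rate", lower = 0, upper = 1, open_upper = TRUE)
  stop_if_not_scalar(geno_error, "geno_error", lower = 0, upper = 1, open_upper = TRUE)
  with_seed(seed, {
    m <- nrow(panel$sites)
    k <- max(1L, round(typed_fraction * m))
    w <- pmax(panel$sites$maf, 1e-6) ^ ascertainment_weight
    typed <- if (k >= m) seq_len(m) else sort(sample.int(m, k, prob = w))
    G <- truth$genotypes[, typed, drop = FALSE]
    n <- length(G)
    if (geno_error > 0) {
      flip <- which(runif(n) < geno_error)
      if (length(flip)) {
        shift <- sample.int(2L, length(flip), replace = TRUE)
        G[flip] <- (G[flip] + shift) %% 3L
      }
    }
    if (miss_rate > 0) G[runif(n) < miss_rate] <- NA_integer_
    structure(list(typed = typed, genotypes = G,
                   sites = panel$sites[typed, , drop = FALSE],
                   missingness = colMeans(is.na(G)),
                   call_rate = rowMeans(!is.na(G)),
                   sample_ids = truth$sample_ids, seed = seed),
              class = "array_genotypes")
  })
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum, over heterozygote counts of the same parity as the
#' observed minor-allele count, of conditional probabilities no larger than
#' that of the observed heterozygote count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative, total >= 1).
#' @return The exact p-value in (0, 1]; monomorphic sites return 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped sample is required")
  n_alt <- 2 * n_aa + n_Aa
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1.0)      # no variation, no deviation
  hets <- seq.int(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | n, rare), Levene-Haldane conditional distribution
  logp <- vapply(hets, function(h) {
    n1 <- (rare - h) / 2          # homozygotes of the rarer allele
    n2 <- n - n1 - h
    lgamma(n + 1) - lgamma(n1 + 1) - lgamma(h + 1) - lgamma(n2 + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pobs <- p[match(n_Aa, hets)]
  if (is.na(pobs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= pobs * (1 + 1e-9)]))
}

#' Array quality-control filters
#'
#' Applies, in this fixed order: (1) drop sites with missingness above
#' `miss_threshold`; (2) drop sites whose Hardy-Weinberg exact-test p-value
#' is below `hwe_alpha`; (3) drop all strand-ambiguous sites (ref/alt pair
#' A/T or C/G); (4) drop samples whose call rate over the surviving sites is
#' below `call_rate_threshold`. Removal counts are reported per filter.
#'
#' @param arr An `array_genotypes`.
#' @param miss_threshold Site missingness cutoff (default 0.05).
#' @param hwe_alpha HWE significance level (default 1e-6).
#' @param call_rate_threshold Sample call-rate cutoff (default 0.97).
#' @return List with `array` (filtered `array_genotypes`) and `report`
#'   (data frame of per-filter removal counts).
#' @export
array_qc <- function(arr, miss_threshold = 0.05, hwe_alpha = 1e-6,
                     call_rate_threshold = 0.97) {
  stopifnot(inherits(arr, "array_genotypes"))
  G <- arr$genotypes
  keep <- seq_len(ncol(G))

  miss <- colMeans(is.na(G[, keep, drop = FALSE]))
  drop_miss <- keep[miss > miss_threshold]
  keep <- setdiff(keep, drop_miss)

  hwe_p <- vapply(keep, function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    if (length(g) == 0) return(1.0)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  drop_hwe <- keep[hwe_p < hwe_alpha]
  keep <- setdiff(keep, drop_hwe)

  pair <- paste0(pmin(arr$sites$ref, arr$sites$alt),
                 pmax(arr$sites$ref, arr$sites$alt))
  drop_amb <- keep[pair[keep] %in% c("AT", "CG")]
  keep <- setdiff(keep, drop_amb)

  if (length(keep) == 0L) {
    counts <- c(missingness = length(drop_miss), hwe = length(drop_hwe),
                ambiguous_strand = length(drop_amb))
    stop("all sites removed by QC; dominating filter: ",
         names(which.max(counts)))
  }

  cr <- rowMeans(!is.na(G[, keep, drop = FALSE]))
  keep_samples <- which(cr >= call_rate_threshold)

  out <- arr
  out$typed <- arr$typed[keep]
  out$genotypes <- G[keep_samples, keep, drop = FALSE]
  out$sites <- arr$sites[keep, , drop = FALSE]
  out$missingness <- colMeans(is.na(out$genotypes))
  out$call_rate <- rowMeans(!is.na(out$genotypes))
  out$sample_ids <- arr$sample_ids[keep_samples]

  report <- data.frame(
    filter = c("missingness", "hwe", "ambiguous_strand", "sample_call_rate"),
    removed = c(length(drop_miss), length(drop_hwe), length(drop_amb),
                length(cr) - length(keep_samples)),
    threshold = c(miss_threshold, hwe_alpha, NA, call_rate_threshold))
  list(array = out, report = report)
}

#' Impute all panel sites from post-QC array genotypes
#'
#' A single forward-backward pass per sample over all panel sites, with
#' near-delta emissions at typed, non-missing sites (weight `1 - epsilon` on
#' the observed genotype) and uniform emissions elsewhere.
#'
#' @param arr A post-QC `array_genotypes`.
#' @param panel A `haplotype_panel`.
#' @param params [hmm_params()].
#' @param epsilon Residual emission weight spread over unobserved genotypes.
#' @param relative_of Named list of panel relatives to exclude per sample.
#' @return A `dosage_matrix`.
#' @export
impute_from_array <- function(arr, panel, params = hmm_params(),
                              epsilon = 1e-3, relative_of = NULL) {
  stopifnot(inherits(arr, "array_genotypes"), inherits(panel, "haplotype_panel"))
  if (ncol(arr$genotypes) == 0L) stop("array has no sites")
  m <- nrow(panel$sites)
  n <- length(arr$sample_ids)
  D <- matrix(NA_real_, n, m, dimnames = list(arr$sample_ids, NULL))
  for (i in seq_len(n)) {
    emis <- matrix(1, m, 3)
    g <- arr$genotypes[i, ]
    obs <- which(!is.na(g))
    if (length(obs)) {
      e <- matrix(epsilon / 2, length(obs), 3)
      e[cbind(seq_along(obs), g[obs] + 1L)] <- 1 - epsilon
      emis[arr$typed[obs], ] <- e
    }
    id <- arr$sample_ids[i]
    excl <- c(id, relative_of[[id]] %||% character(0),
              names(Filter(function(v) id %in% v, panel$pedigree)))
    keep <- setdiff(panel$sample_ids, excl)
    rows <- hap_rows(match(keep, panel$sample_ids))
    fb <- forward_backward(emis, panel$haplotypes[rows, , drop = FALSE],
                           panel$genetic_map, params)
    D[i, ] <- fb$dosage
  }
  structure(list(dosage = D, sites = panel$sites, sample_ids = arr$sample_ids,
                 covered = rep(list(arr$typed), n), posterior = NULL,
                 provenance = list(stage = "array", params = unclass(params),
                                   epsilon = epsilon)),
            class = "dosage_matrix")
}
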