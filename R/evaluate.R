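#' Dosage r-squared between imputed dosages and true genotypes
#'
#' Squared Pearson correlation along the requested axis. Samples are matched
#' by id; sites are assumed aligned (both objects derive from the same
#' panel). Entries with zero variance on either side are reported as `NA`,
#' never as 0 or 1. A negative underlying correlation is flagged via the
#' `r` column.
#'
#' @param dosages A `dosage_matrix`.
#' @param truth A `truth_genotypes`.
#' @param axis `"per_sample"` (correlate across sites within each sample) or
#'   `"per_site"` (across samples within each site).
#' @return Data frame with `id` (sample id or site index), `r2`, `r`, `n`.
#' @export
dosage_r2 <- function(dosages, truth, axis = c("per_sample", "per_site")) {
  axis <- match.arg(axis)
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(truth, "truth_genotypes"))
  shared <- intersect(dosages$sample_ids, truth$sample_ids)
  if (length(shared) == 0L) stop("no overlapping samples between dosages and truth")
  D <- dosages$dosage[match(shared, dosages$sample_ids), , drop = FALSE]
  G <- truth$genotypes[match(shared, truth$sample_ids), , drop = FALSE]
  if (ncol(D) != ncol(G)) stop("dosages and truth disagree on site count")
  one <- function(d, g) {
    if (length(d) < 2 || sd(d) == 0 || sd(g) == 0) return(c(NA_real_, NA_real_))
    r <- cor(d, g)
    c(r * r, r)
  }
  if (axis == "per_sample") {
    vals <- t(vapply(seq_len(nrow(D)), function(i) one(D[i, ], G[i, ]),
                     numeric(2)))
    data.frame(id = shared, r2 = vals[, 1], r = vals[, 2], n = ncol(D),
               stringsAsFactors = FALSE)
  } else {
    vals <- t(vapply(seq_len(ncol(D)), function(j) one(D[, j], G[, j]),
                     numeric(2)))
    data.frame(id = seq_len(ncol(D)), r2 = vals[, 1], r = vals[, 2],
               n = nrow(D))
  }
}

#' Stratify per-site accuracy by minor-allele-frequency bucket
#'
#' Buckets by folded global panel MAF with half-open edges: rare `(0,
#' 0.01]`, low `(0.01, 0.05]`, common `(0.05, 0.5]`. A MAF of exactly 0.05
#' falls in the low bucket and exactly 0.01 in the rare bucket.
#'
#' @param per_site Data frame from `dosage_r2(..., axis = "per_site")`.
#' @param maf Folded global MAF per site (e.g. `panel$sites$maf`).
#' @return Data frame with one row per bucket: `bucket`, `mean_r2`,
#'   `n_sites` (sites with defined r2), `n_excluded` (zero-variance sites).
#' @export
maf_buckets <- function(per_site, maf) {
  if (nrow(per_site) != length(maf))
    stop("`maf` must have one value per site in `per_site`")
  bucket <- cut(maf, breaks = c(0, 0.01, 0.05, 0.5),
                labels = c("rare_lt_1pct", "low_1_5pct", "common_gt_5pct"),
                right = TRUE)
  out <- lapply(levels(bucket), function(b) {
    r2 <- per_site$r2[which(bucket == b)]
    data.frame(bucket = b, mean_r2 = mean(r2, na.rm = TRUE),
               n_sites = sum(!is.na(r2)), n_excluded = sum(is.na(r2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Concordance between two paired polygenic score vectors
#'
#' Reports the squared Pearson correlation, a Student's two-sample t test of
#' mean equality (equal variances), and an F test of variance equality.
#'
#' @param scores_a,scores_b Paired numeric score vectors (same samples).
#' @return List with `r2`, `r`, `t_p` and `t_stat`, `f_p` and `f_stat`, `n`.
#' @export
gps_concordance <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("score vectors differ in length")
  if (length(scores_a) < 3L) stop("need at least 3 paired samples")
  if (sd(scores_a) == 0 || sd(scores_b) == 0)
    stop("zero variance in a score vector")
  r <- cor(scores_a, scores_b)
  tt <- t.test(scores_a, scores_b, var.equal = TRUE)
  ft <- var.test(scores_a, scores_b)
  list(r2 = r * r, r = r, t_stat = unname(tt$statistic), t_p = tt$p.value,
       f_stat = unname(ft$statistic), f_p = ft$p.value, n = length(scores_a))
}

#' Imputation accuracy across a coverage ladder
#'
#' For each seed, master pileups are simulated at the top of the ladder and
#' binomially thinned down to each rung (so rungs share reads, as when
#' downsampling a real sequencing run); each rung is imputed with the full
#' two-stage pipeline and summarized as the mean per-sample dosage r2.
#' The confidence interval is a normal approximation over seed replicates.
#'
#' @param panel A `haplotype_panel`.
#' @param truth Target `truth_genotypes` (held-out samples).
#' @param ladder Coverage rungs; default `c(2, 1, 0.75, 0.5, 0.4, 0.25,
#'   0.1)`.
#' @param seeds Integer vector of simulation seeds (>= 1 rung replicates).
#' @param params,panel_size,base_error Passed to the pipeline stages.
#' @return Data frame with `coverage`, `mean_r2`, `ci_lo`, `ci_hi`,
#'   `n_seeds`, plus a `per_seed` attribute with the seed-level means.
#' @export
coverage_curve <- function(panel, truth, ladder = c(2, 1, 0.75, 0.5, 0.4, 0.25, 0.1),
                           seeds = c(1L, 2L), params = hmm_params(),
                           panel_size = 250L, base_error = 0.005) {
  if (length(ladder) == 0L) stop("coverage ladder is empty")
  ladder <- sort(unique(ladder), decreasing = TRUE)
  res <- matrix(NA_real_, length(seeds), length(ladder),
                dimnames = list(NULL, format(ladder)))
  for (si in seq_along(seeds)) {
    master <- simulate_pileups(truth, max(ladder), base_error = base_error,
                               seed = seeds[si])
    for (ci in seq_along(ladder)) {
      pl <- tryCatch(
        downsample_pileups(master, ladder[ci], seed = seeds[si] + 1000L * ci),
        error = function(e) stop(sprintf("coverage %.2f seed %d: %s",
                                         ladder[ci], seeds[si],
                                         conditionMessage(e)), call. = FALSE))
      dm <- impute_cohort(pl, panel, params = params, panel_size = panel_size,
                          relative_of = truth$relative_of)
      res[si, ci] <- mean(dosage_r2(dm, truth, "per_sample")$r2, na.rm = TRUE)
    }
  }
  mu <- colMeans(res)
  se <- apply(res, 2L, sd) / sqrt(length(seeds))
  se[!is.finite(se)] <- 0
  out <- data.frame(coverage = ladder, mean_r2 = as.numeric(mu),
                    ci_lo = as.numeric(mu - qnorm(0.975) * se),
                    ci_hi = as.numeric(mu + qnorm(0.975) * se),
                    n_seeds = length(seeds))
  out <- out[order(out$coverage), ]
  rownames(out) <- NULL
  attr(out, "per_seed") <- res
  out
}
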