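#' Simulate low-coverage sequencing pileups
#'
#' Per-site read depth is Poisson at the nominal coverage. Each read draws
#' one of the sample's two true alleles at the site, is emitted as a
#' non-ref/non-alt base with probability `frac_other`, and otherwise has its
#' allele flipped (ref <-> alt) with probability `base_error`. Only reads
#' that would pass mapping/base-quality filtering are emitted; quality
#' filtering is folded into the generator since no aligner is in scope.
#'
#' @param truth A `truth_genotypes` object.
#' @param coverage Nominal mean reads per site (> 0).
#' @param base_error Per-read probability of reporting the opposite allele.
#' @param frac_other Per-read probability of a base matching neither allele
#'   (such reads are discarded downstream).
#' @param seed Integer seed.
#' @return A `pileup_set`: list with integer count matrices `n_ref`,
#'   `n_alt`, `n_other` (samples x sites), `sample_ids`, `sites`,
#'   `nominal_coverage`, and seed provenance.
#' @export
simulate_pileups <- function(truth, coverage, base_error = 0.005,
                             frac_other = 0.002, seed = 1L) {
  stopifnot(inherits(truth, "truth_genotypes"))
  stop_if_not_scalar(coverage, "coverage", lower = 0, open_lower = TRUE)
  stop_if_not_scalar(base_error, "base_error", lower = 0, upper = 0.5,
                     open_upper = TRUE)
  stop_if_not_scalar(frac_other, "frac_other", lower = 0, upper = 1,
                     open_upper = TRUE)
  with_seed(seed, {
    g <- truth$genotypes
    n <- nrow(g); m <- ncol(g)
    depth <- matrix(rpois(n * m, coverage), n, m)
    n_other <- matrix(rbinom(n * m, depth, frac_other), n, m)
    rest <- depth - n_other
    # P(alt | genotype) after the ref<->alt error flip
    p_alt <- (g / 2) * (1 - base_error) + (1 - g / 2) * base_error
    n_alt <- matrix(rbinom(n * m, rest, as.vector(p_alt)), n, m)
    n_ref <- rest - n_alt
    dimnames(n_ref) <- dimnames(n_alt) <- dimnames(n_other) <-
      list(truth$sample_ids, NULL)
    structure(list(n_ref = n_ref, n_alt = n_alt, n_other = n_other,
                   sample_ids = truth$sample_ids, sites = truth$sites,
                   nominal_coverage = coverage, base_error = base_error,
                   seed = seed), class = "pileup_set")
  })
}

#' Downsample pileups to a lower target coverage
#'
#' Binomial thinning: every read is kept independently with probability
#' `min(1, target / realized)` where realized is that sample's mean total
#' read count per site. Samples whose realized coverage is already at or
#' below the target are returned unchanged (all reads retained).
#'
#' @param pileups A `pileup_set`.
#' @param target_coverage Target mean coverage (> 0).
#' @param seed Integer seed; distinct seeds give independent thinnings.
#' @return A `pileup_set` at the reduced coverage.
#' @export
downsample_pileups <- function(pileups, target_coverage, seed = 1L) {
  stopifnot(inherits(pileups, "pileup_set"))
  stop_if_not_scalar(target_coverage, "target_coverage", lower = 0,
                     open_lower = TRUE)
  with_seed(seed, {
    out <- pileups
    realized <- rowMeans(pileups$n_ref + pileups$n_alt + pileups$n_other)
    for (i in seq_along(realized)) {
      p <- target_coverage / realized[i]
      if (!is.finite(p) || p >= 1) next   # retention rule: keep everything
      for (fld in c("n_ref", "n_alt", "n_other")) {
        cnt <- pileups[[fld]][i, ]
        out[[fld]][i, ] <- rbinom(length(cnt), cnt, p)
      }
    }
    out$nominal_coverage <- target_coverage
    out$seed <- seed
    out
  })
}

#' Coverage quality control
#'
#' A sample fails QC when its realized mean coverage (mean total reads per
#' site, including discarded "other" bases) is below `min_coverage`. The
#' default threshold of 0.5x is the package's standard cutoff for a usable
#' low-coverage sample.
#'
#' @param pileups A `pileup_set`.
#' @param min_coverage Minimum acceptable realized mean coverage.
#' @return Data frame with `sample_id`, `realized_coverage`, `pass`.
#' @export
coverage_qc <- function(pileups, min_coverage = 0.5) {
  stopifnot(inherits(pileups, "pileup_set"))
  realized <- rowMeans(pileups$n_ref + pileups$n_alt + pileups$n_other)
  data.frame(sample_id = pileups$sample_ids,
             realized_coverage = as.numeric(realized),
             pass = realized >= min_coverage,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write pileup counts as tab-separated text
#'
#' Columns `sample chrom pos n_ref n_alt n_other`; only sites with at least
#' one read are written. This is also the real-data entry format: any
#' external pileup tool can produce it.
#'
#' @param pileups A `pileup_set`.
#' @param path Output file path.
#' @export
write_pileups <- function(pileups, path) {
  stopifnot(inherits(pileups, "pileup_set"))
  tot <- pileups$n_ref + pileups$n_alt + pileups$n_other
  rows <- which(tot > 0, arr.ind = TRUE)
  df <- data.frame(sample = pileups$sample_ids[rows[, 1]],
                   chrom = pileups$sites$chrom[rows[, 2]],
                   pos = pileups$sites$pos[rows[, 2]],
                   n_ref = pileups$n_ref[rows], n_alt = pileups$n_alt[rows],
                   n_other = pileups$n_other[rows])
  df <- df[order(df$sample, df$pos), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pileup counts written by [write_pileups()]
#'
#' @param path File path.
#' @param sites Site table the counts refer to (e.g. `panel$sites`); rows are
#'   matched by `chrom` and `pos`.
#' @param nominal_coverage Optional nominal coverage annotation.
#' @return A `pileup_set`.
#' @export
read_pileups <- function(path, sites, nominal_coverage = NA_real_) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "n_ref", "n_alt", "n_other")
  if (!all(need %in% names(df)))
    stop("pileup file must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$sample)
  key <- paste(sites$chrom, sites$pos)
  j <- match(paste(df$chrom, df$pos), key)
  if (anyNA(j))
    stop("pileup file contains positions absent from the site table")
  i <- match(df$sample, ids)
  mk <- function(v) {
    m <- matrix(0L, length(ids), nrow(sites), dimnames = list(ids, NULL))
    m[cbind(i, j)] <- as.integer(v)
    m
  }
  structure(list(n_ref = mk(df$n_ref), n_alt = mk(df$n_alt),
                 n_other = mk(df$n_other), sample_ids = ids, sites = sites,
                 nominal_coverage = nominal_coverage, base_error = NA_real_,
                 seed = NA_integer_), class = "pileup_set")
}
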