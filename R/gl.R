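#' Genotype likelihoods from pileup counts
#'
#' Converts filtered per-site read counts into likelihoods over genotypes
#' g in {0, 1, 2} (alternate-allele count). Reads matching neither allele
#' (`n_other`) are discarded. With k retained reference reads, m retained
#' alternate reads and error rate e:
#' \deqn{L^*(0) = (1-e)^k e^m,\quad L^*(1) = 0.5^{k+m},\quad
#'       L^*(2) = e^k (1-e)^m}
#' Likelihoods are normalized so the maximum is 1. Sites with no retained
#' reads are omitted. Error mass goes entirely to the opposite allele
#' because non-ref/alt bases were already discarded.
#'
#' @param pileups A `pileup_set`.
#' @param error_rate Post-filter per-read error probability, in (0, 0.5).
#' @return A `gl_set`: list with one element per sample, each a list with
#'   `sample_id`, `covered` (0-based free, here 1-based site indices into
#'   the panel site table), `lik` (length(covered) x 3 matrix, max 1 per
#'   row), and the `error_rate` used.
#' @export
compute_gl <- function(pileups, error_rate = 0.005) {
  stopifnot(inherits(pileups, "pileup_set"))
  stop_if_not_scalar(error_rate, "error_rate", lower = 0, upper = 0.5,
                     open_lower = TRUE, open_upper = TRUE)
  if (any(pileups$n_ref < 0) || any(pileups$n_alt < 0) || any(pileups$n_other < 0))
    stop("negative read counts")
  e <- error_rate
  per_sample <- lapply(seq_along(pileups$sample_ids), function(i) {
    k <- pileups$n_ref[i, ]
    m <- pileups$n_alt[i, ]
    covered <- which(k + m > 0L)
    k <- k[covered]; m <- m[covered]
    # log-domain then normalize to max = 1 (no underflow at any depth)
    l0 <- k * log1p(-e) + m * log(e)
    l1 <- (k + m) * log(0.5)
    l2 <- k * log(e) + m * log1p(-e)
    mx <- pmax(l0, l1, l2)
    lik <- cbind(exp(l0 - mx), exp(l1 - mx), exp(l2 - mx))
    colnames(lik) <- c("g0", "g1", "g2")
    list(sample_id = pileups$sample_ids[i], covered = covered, lik = lik,
         error_rate = e)
  })
  structure(list(samples = per_sample, sample_ids = pileups$sample_ids,
                 sites = pileups$sites, error_rate = e), class = "gl_set")
}

# posterior-mean alt dosage under a uniform genotype prior; full-length
# vector with NA at uncovered sites (used for IBS comparison)
gl_dosage <- function(gl_sample, n_sites) {
  d <- rep(NA_real_, n_sites)
  lik <- gl_sample$lik
  tot <- rowSums(lik)
  d[gl_sample$covered] <- (lik[, 2] + 2 * lik[, 3]) / tot
  d
}
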