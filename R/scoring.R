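# extract a samples x sites numeric genotype/dosage matrix plus site table
geno_of <- function(x) {
  if (inherits(x, "dosage_matrix")) list(g = x$dosage, sites = x$sites,
                                         ids = x$sample_ids)
  else if (inherits(x, "truth_genotypes")) list(g = x$genotypes, sites = x$sites,
                                                ids = x$sample_ids)
  else stop("expected a `dosage_matrix` or `truth_genotypes`")
}

#' Compute raw polygenic scores from dosages
#'
#' `raw = sum_j w_j * d_j(effect)` where the effect dosage is the alternate
#' dosage when the effect allele is the alternate allele and `2 - dosage`
#' when it is the reference allele. Every score entry must resolve against
#' the site table; no site is ever dropped for low imputation quality.
#'
#' @param x A `dosage_matrix` or `truth_genotypes`.
#' @param score A `score_definition`.
#' @return Named numeric vector of raw scores.
#' @export
compute_gps <- function(x, score) {
  stopifnot(inherits(score, "score_definition"))
  dat <- geno_of(x)
  key <- paste(dat$sites$chrom, dat$sites$pos, dat$sites$ref, dat$sites$alt)
  idx <- match(paste(score$chrom, score$pos, score$ref, score$alt), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("score sites not present in the dosage site table: ",
         paste(sprintf("%s:%d", score$chrom[bad], score$pos[bad])[
           seq_len(min(5, length(bad)))], collapse = ", "))
  }
  D <- dat$g[, idx, drop = FALSE]
  eff_is_alt <- score$effect_allele == score$alt
  Deff <- sweep(D, 2L, ifelse(eff_is_alt, 0, 2), function(d, c) abs(c - d))
  raw <- as.numeric(Deff %*% score$weight)
  stats::setNames(raw, dat$ids)
}

#' Project samples into a reference principal-component space
#'
#' The reference PCA is computed on the panel's genotype matrix with each
#' site centered by `2 * p_hat` and scaled by `sqrt(2 * p_hat * (1 -
#' p_hat))` (`p_hat` = panel alternate-allele frequency). Cohort samples are
#' projected onto the reference loadings using their dosages with the same
#' centering and scaling. Zero-variance panel sites are excluded and
#' reported.
#'
#' @param x Cohort `dosage_matrix` or `truth_genotypes`.
#' @param panel Reference `haplotype_panel`.
#' @param n_pcs Number of principal components (default 10).
#' @return List with `coords` (cohort samples x n_pcs), `ref_coords` (panel
#'   samples x n_pcs), `loadings`, `sites_used`, `n_excluded`.
#' @export
pc_project <- function(x, panel, n_pcs = 10L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  stop_if_not_scalar(n_pcs, "n_pcs", lower = 1)
  dat <- geno_of(x)
  if (ncol(dat$g) != nrow(panel$sites))
    stop("cohort matrix and panel disagree on site count")
  Gp <- haps_to_genotypes(panel$haplotypes)
  p_hat <- colMeans(Gp) / 2
  use <- which(p_hat > 0 & p_hat < 1)
  n_excluded <- nrow(panel$sites) - length(use)
  ctr <- 2 * p_hat[use]
  scl <- sqrt(2 * p_hat[use] * (1 - p_hat[use]))
  Zp <- sweep(sweep(Gp[, use, drop = FALSE], 2L, ctr), 2L, scl, "/")
  if (n_pcs > min(dim(Zp)))
    stop(sprintf("n_pcs = %d exceeds the rank bound %d", n_pcs, min(dim(Zp))))
  sv <- svd(Zp, nu = n_pcs, nv = n_pcs)
  loadings <- sv$v
  ref_coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  Zc <- sweep(sweep(dat$g[, use, drop = FALSE], 2L, ctr), 2L, scl, "/")
  coords <- Zc %*% loadings
  colnames(coords) <- colnames(ref_coords) <- paste0("PC", seq_len(n_pcs))
  rownames(coords) <- dat$ids
  rownames(ref_coords) <- panel$sample_ids
  list(coords = coords, ref_coords = ref_coords, loadings = loadings,
       sites_used = use, n_excluded = n_excluded)
}

#' Normalize polygenic scores as principal-component residual z-scores
#'
#' Ordinary least squares of the raw score on the principal components (with
#' intercept); the normalized score is the residual divided by the residual
#' standard deviation, so the cohort has mean 0 and SD 1.
#'
#' @param raw Named numeric vector of raw scores.
#' @param pcs Matrix of per-sample PC coordinates (samples x n_pcs).
#' @return Named numeric vector of normalized scores, with an
#'   `outlier_flag` attribute marking |z| > 5 (flagged, never dropped).
#' @export
normalize_gps <- function(raw, pcs) {
  pcs <- as.matrix(pcs)
  if (length(raw) != nrow(pcs)) stop("`raw` and `pcs` disagree on sample count")
  if (length(raw) < ncol(pcs) + 2L)
    stop("need at least n_pcs + 2 samples to fit the PC regression")
  fit <- lm(raw ~ pcs)
  if (anyNA(coef(fit)))
    stop("collinear principal components; reduce n_pcs")
  res <- stats::residuals(fit)
  s <- sd(res)
  if (!is.finite(s) || s <= 1e-10 * max(sd(raw), .Machine$double.xmin))
    stop("zero residual variance: score is an exact function of the PCs")
  z <- stats::setNames(as.numeric(res / s), names(raw))
  attr(z, "outlier_flag") <- abs(z) > 5
  z
}

#' Association of a normalized score with a binary phenotype
#'
#' Maximum-likelihood logistic regression of the phenotype on the normalized
#' score plus covariates. Reports the odds ratio per standard deviation
#' (`exp` of the score coefficient), its Wald 95% confidence interval and
#' p-value, the AUC of the score alone, and the AUC of the full model's
#' linear predictor. AUC is the rank statistic: the probability that a
#' random case outscores a random control, ties split.
#'
#' @param normalized Numeric vector of normalized scores.
#' @param phenotypes A `phenotype_set` (or data frame with a `phenotype`
#'   column of 0/1).
#' @param covariates Character vector of covariate column names in
#'   `phenotypes` to adjust for (e.g. `c("age", "sex")`), or `NULL`.
#' @return List with `or_per_sd`, `ci` (length 2), `p_value`, `auc_score`,
#'   `auc_full`, `n`, and the fitted `model`.
#' @export
associate_gps <- function(normalized, phenotypes, covariates = NULL) {
  y <- phenotypes$phenotype
  if (length(unique(y)) < 2L) stop("both phenotype classes must be present")
  df <- data.frame(y = y, score = as.numeric(normalized))
  for (cv in covariates) df[[cv]] <- phenotypes[[cv]]
  fit <- glm(y ~ ., data = df, family = binomial())
  b <- coef(fit)["score"]
  se <- sqrt(vcov(fit)["score", "score"])
  if (!is.finite(se) || se > 50 || abs(b) > 20)
    stop("(quasi-)perfect separation in the logistic fit; the score separates ",
         "cases and controls exactly - refit on more samples or check the inputs")
  list(or_per_sd = exp(unname(b)),
       ci = exp(unname(b) + c(-1, 1) * qnorm(0.975) * se),
       p_value = unname(2 * pnorm(-abs(b / se))),
       auc_score = rank_auc(df$score, y),
       auc_full = rank_auc(stats::predict(fit, type = "link"), y),
       n = length(y), model = fit)
}

# AUC by the Mann-Whitney rank statistic, midranks split ties
rank_auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write per-sample scores as tab-separated text
#'
#' Columns `sample raw_score normalized_score flag_outlier`.
#'
#' @param raw,normalized Aligned named score vectors.
#' @param path Output path.
#' @export
write_scores <- function(raw, normalized, path) {
  df <- data.frame(sample = names(raw) %||% seq_along(raw),
                   raw_score = sprintf("%.6g", raw),
                   normalized_score = sprintf("%.6g", normalized),
                   flag_outlier = as.logical(attr(normalized, "outlier_flag") %||%
                                               (abs(normalized) > 5)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
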