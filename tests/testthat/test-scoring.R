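toy_dosages <- function(D, sites) {
  structure(list(dosage = D, sites = sites,
                 sample_ids = rownames(D) %||% sprintf("S%d", seq_len(nrow(D))),
                 covered = list(), posterior = NULL,
                 provenance = list(stage = "toy")), class = "dosage_matrix")
}

toy_score <- function(sites, effect_allele, weight) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = sites$alt, effect_allele = effect_allele,
                    weight = weight, stringsAsFactors = FALSE)
  class(out) <- c("score_definition", "data.frame")
  out
}

test_that("raw GPS follows the weighted effect-dosage sum", {
  sites <- data.frame(chrom = "chrS", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  D <- matrix(c(2, 2, 0.5), 1, 3)
  sc <- toy_score(sites, effect_allele = c("G", "A", "G"),
                  weight = c(0.5, -1.0, 2.0))
  # 0.5*2 + (-1)*(2-2) + 2*0.5 = 2.0
  expect_equal(unname(compute_gps(toy_dosages(D, sites), sc)), 2.0)

  # zero weights give zero scores
  sc0 <- toy_score(sites, c("G", "A", "G"), c(0, 0, 0))
  expect_equal(unname(compute_gps(toy_dosages(D, sites), sc0)), 0)

  # flipping an entry's effect allele and negating its weight shifts every
  # sample by a constant 2w, leaving score differences invariant
  D2 <- rbind(c(2, 2, 0.5), c(1, 0, 1.5))
  sc_flip <- sc
  sc_flip$effect_allele[3] <- "A"
  sc_flip$weight[3] <- -sc$weight[3]
  a <- compute_gps(toy_dosages(D2, sites), sc)
  b <- compute_gps(toy_dosages(D2, sites), sc_flip)
  expect_equal(unname(diff(a)), unname(diff(b)), tolerance = 1e-12)
  expect_equal(unname(b - a), rep(-2 * sc$weight[3], 2), tolerance = 1e-12)

  # linearity in weights
  sc_sum <- sc
  sc_sum$weight <- sc$weight + sc0$weight + c(1, 1, 1)
  one <- toy_score(sites, c("G", "A", "G"), c(1, 1, 1))
  expect_equal(compute_gps(toy_dosages(D2, sites), sc_sum),
               compute_gps(toy_dosages(D2, sites), sc) +
                 compute_gps(toy_dosages(D2, sites), one),
               tolerance = 1e-12)

  sc_bad <- toy_score(data.frame(chrom = "chrS", pos = 99L, ref = "A",
                                 alt = "G"), "G", 1)
  expect_error(compute_gps(toy_dosages(D, sites), sc_bad), "chrS:99")
})

test_that("PC projection recovers reference coordinates and separates populations", {
  pan <- small_panel()$panel
  truth <- small_panel()$truth
  pcs <- pc_project(truth, pan, n_pcs = 5L)
  # projecting the panel samples themselves recovers the reference PCA
  expect_lt(max(abs(pcs$coords - pcs$ref_coords)), 1e-6)

  # two-population panel with drift: PC1 separates the labels
  cfg2 <- sim_config(n_founders = 30L, n_panel_samples = 80L, n_sites = 800L,
                     region_length_bp = 2e6,
                     population_spec = list(labels = c("A", "B"), drift = 0.05),
                     seed = 13L)
  p2 <- generate_panel(cfg2)
  pc2 <- pc_project(p2$truth, p2$panel, n_pcs = 2L)
  lab <- as.numeric(p2$panel$population_of == "A")
  expect_gt(abs(cor(pc2$coords[, 1], lab)), 0.9)

  expect_error(pc_project(truth, pan, n_pcs = 1e6), "rank")
})

test_that("normalization reduces a planted ancestry confound and handles edge cases", {
  pan <- small_panel()$panel
  truth <- small_panel()$truth
  pcs <- pc_project(truth, pan, n_pcs = 10L)

  # PCs orthogonal to the score: normalization is plain standardization
  set.seed(33)
  raw <- rnorm(length(pan$sample_ids))
  raw_orth <- stats::residuals(lm(raw ~ pcs$coords))
  z <- normalize_gps(raw_orth, pcs$coords)
  expect_equal(as.numeric(z), as.numeric(scale(raw_orth)), tolerance = 1e-8)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-6)

  # score that is an exact linear function of PC1 -> zero residual variance
  expect_error(normalize_gps(3 * pcs$coords[, 1], pcs$coords), "residual")

  # planted confound: effect alleles oriented toward one population
  sc <- generate_score(pan, 200L, seed = 14L,
                       confound_populations = c("POPA", "POPB"))
  rawc <- compute_gps(truth, sc)
  zn <- normalize_gps(rawc, pcs$coords)
  z0 <- as.numeric(scale(rawc))
  pop <- pan$population_of
  gap <- function(v) abs(mean(v[pop == "POPA"]) - mean(v[pop == "POPB"]))
  expect_gt(1 - gap(zn) / gap(z0), 0.9)

  # outliers are flagged, never dropped
  raw2 <- c(raw_orth[-1], 60 * max(abs(raw_orth)))
  z2 <- normalize_gps(raw2, pcs$coords)
  expect_length(z2, length(raw2))
  expect_true(any(attr(z2, "outlier_flag")))
})

test_that("association reports OR per SD and rank-statistic AUC", {
  set.seed(44)
  n <- 180
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * z))
  ph <- data.frame(phenotype = y, age = rnorm(n, 55, 8),
                   sex = rbinom(n, 1, 0.5))
  a <- associate_gps(z, ph, covariates = c("age", "sex"))
  # AUC equals the O(n^2) pairwise oracle exactly
  expect_equal(a$auc_score, pairwise_auc_oracle(z, y), tolerance = 1e-12)
  expect_true(a$ci[1] < a$or_per_sd && a$or_per_sd < a$ci[2])

  # null case: large-sample AUC near 0.5 and CI covering OR 1
  set.seed(45)
  z0 <- rnorm(4000)
  y0 <- rbinom(4000, 1, 0.15)
  a0 <- associate_gps(z0, data.frame(phenotype = y0))
  expect_lt(abs(a0$auc_score - 0.5), 0.03)
  expect_true(a0$ci[1] <= 1 && 1 <= a0$ci[2])

  expect_error(associate_gps(z0, data.frame(phenotype = rep(1, 4000))),
               "both phenotype classes")
  # perfect separation is reported with guidance
  ys <- as.integer(z[1:40] > 0)
  expect_error(suppressWarnings(associate_gps(z[1:40], data.frame(phenotype = ys))),
               "separation")
})
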