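test_that("panel generation is deterministic and respects the site filter", {
  cfg <- small_config(seed = 31L)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)

  pan <- p1$panel
  # every retained site has alt AF >= threshold in at least one population
  afm <- as.matrix(pan$sites[grep("^af_", names(pan$sites), value = TRUE)])
  afm <- afm[, setdiff(colnames(afm), "af_global"), drop = FALSE]
  expect_true(all(apply(afm >= cfg$maf_filter_threshold, 1, any)))
  # no monomorphic sites
  expect_true(all(pan$sites$af_global > 0 & pan$sites$af_global < 1))

  # threshold 0 disables the frequency filter (monomorphic still dropped)
  cfg0 <- small_config(seed = 31L, maf_filter_threshold = 0)
  pan0 <- generate_panel(cfg0)$panel
  expect_gte(nrow(pan0$sites), nrow(pan$sites))
  expect_true(all(pan0$sites$af_global > 0 & pan0$sites$af_global < 1))
})

test_that("stored per-population frequencies match direct allele counting", {
  pan <- small_panel()$panel
  for (pop in unique(pan$population_of)) {
    idx <- which(pan$population_of == pop)
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    recount <- colMeans(pan$haplotypes[rows, , drop = FALSE])
    expect_equal(unname(recount), pan$sites[[paste0("af_", pop)]],
                 tolerance = 1e-12)
  }
})

test_that("population drift produces real frequency differences", {
  pan <- small_panel()$panel
  a <- pan$sites$af_POPA
  b <- pan$sites$af_POPB
  expect_gt(mean(abs(a - b)), 0.01)
})

test_that("adjacent-site LD decreases as the mosaic switch rate increases", {
  ld_at <- function(rate) {
    cfg <- sim_config(n_founders = 20L, n_panel_samples = 60L, n_sites = 400L,
                      region_length_bp = 2e6, mosaic_switch_rate = rate,
                      population_spec = list(labels = "POP", drift = 0),
                      seed = 77L)
    pan <- generate_panel(cfg)$panel
    g <- pan$haplotypes[seq(1, nrow(pan$haplotypes), 2), ] +
      pan$haplotypes[seq(2, nrow(pan$haplotypes), 2), ]
    m <- ncol(g)
    keep <- which(apply(g, 2, sd) > 0)
    keep <- keep[keep < m & (keep + 1) %in% keep]
    mean(vapply(keep, function(j) abs(cor(g[, j], g[, j + 1])), numeric(1)),
         na.rm = TRUE)
  }
  lds <- vapply(c(0.5, 5, 50), ld_at, numeric(1))
  expect_true(all(diff(lds) < 0))
})

test_that("targets are mosaic diploids; relatives share an unrecombined haplotype", {
  tg <- small_targets()
  truth <- tg$truth
  pan <- tg$panel
  expect_true(all(truth$genotypes %in% 0:2))
  # genotype equals the sum of the two emitted haplotypes
  n <- length(truth$sample_ids)
  h1 <- truth$haplotypes[seq(1, 2 * n, 2), ]
  h2 <- truth$haplotypes[seq(2, 2 * n, 2), ]
  expect_identical(truth$genotypes, h1 + h2, ignore_attr = TRUE)
  # targets are not panel members
  expect_length(intersect(truth$sample_ids, pan$sample_ids), 0)
  # relatives recorded symmetrically and sharing an exact haplotype
  expect_length(truth$relative_of, 2L)
  for (tid in names(truth$relative_of)) {
    parent <- truth$relative_of[[tid]]
    expect_true(tid %in% pan$pedigree[[parent]])
    ti <- match(tid, truth$sample_ids)
    pi <- match(parent, pan$sample_ids)
    child_h1 <- truth$haplotypes[2 * ti - 1, ]
    parent_haps <- pan$haplotypes[c(2 * pi - 1, 2 * pi), , drop = FALSE]
    expect_true(any(apply(parent_haps, 1, function(h) all(h == child_h1))))
  }
  # no relatives requested -> no pedigree additions
  tg0 <- generate_targets(small_panel()$panel, n = 3L, n_relatives = 0L, seed = 5L)
  expect_true(all(lengths(tg0$panel$pedigree) == 0))
  expect_length(tg0$truth$relative_of, 0)
  expect_error(generate_targets(small_panel()$panel, n = 2L, n_relatives = 3L),
               "n_relatives")
})

test_that("score generation covers orientation handling and round-trips", {
  pan <- small_panel()$panel
  m <- nrow(pan$sites)
  sc <- generate_score(pan, 50L, weight_scale = 0.2, seed = 9L)
  expect_equal(nrow(sc), 50L)
  expect_true(all(sc$effect_allele == sc$alt | sc$effect_allele == sc$ref))
  expect_equal(sum(sc$effect_allele == sc$alt), 25L)

  sc0 <- generate_score(pan, 10L, weight_scale = 0, seed = 9L)
  expect_true(all(sc0$weight == 0))

  sc_all <- generate_score(pan, m, seed = 2L)
  expect_equal(sort(sc_all$pos), sort(pan$sites$pos))
  expect_error(generate_score(pan, m + 1L), "exceeds")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_file(sc, path)
  sc2 <- read_score_file(path)
  expect_identical(sc$weight, sc2$weight)   # bit-identical round trip
  expect_identical(sc$pos, sc2$pos)
})

test_that("phenotype generator calibrates prevalence and the null case", {
  raw <- stats::setNames(rnorm(20000), sprintf("S%05d", 1:20000))
  ph <- generate_phenotypes(raw, true_or_per_sd = 1.6, prevalence = 0.1,
                            seed = 41L)
  expect_lt(abs(mean(ph$phenotype) - 0.1), 0.02)

  # OR = 1.0: refitted association covers the null
  ph0 <- generate_phenotypes(raw, true_or_per_sd = 1.0, prevalence = 0.2,
                             seed = 42L)
  fit <- glm(ph0$phenotype ~ as.numeric(scale(raw)), family = binomial())
  ci <- exp(coef(fit)[2] + c(-1, 1) * 1.96 * sqrt(vcov(fit)[2, 2]))
  expect_true(ci[1] <= 1 && 1 <= ci[2])

  expect_error(generate_phenotypes(raw, 1.6, 1.2), "prevalence")
  expect_error(generate_phenotypes(raw, -1, 0.1), "true_or_per_sd")
})
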