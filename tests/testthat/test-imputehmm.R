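test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    K <- sample(1:3, 1); M <- sample(1:4, 1)
    hap <- matrix(rbinom(K * M, 1, 0.5), K, M)
    emis <- matrix(runif(M * 3, 0.01, 1), M, 3)
    gmap <- runif(max(0, M - 1), 0.01, 2)
    params <- hmm_params(lambda = runif(1, 1e-4, 0.2))
    got <- forward_backward(emis, hap, gmap, params)$posterior
    want <- brute_force_posterior(emis, hap, gmap, params)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("degenerate single-haplotype panel copies its template exactly", {
  hap <- matrix(c(1L, 0L, 1L), 1, 3)
  emis <- matrix(1, 3, 3)
  fb <- forward_backward(emis, hap, c(0.1, 0.1), hmm_params(lambda = 1e-9))
  expect_equal(fb$posterior[cbind(1:3, 2 * hap[1, ] + 1)], rep(1, 3),
               tolerance = 1e-6)
  expect_equal(fb$dosage, 2 * hap[1, ], tolerance = 1e-6)
})

test_that("posteriors are invariant to panel haplotype permutation", {
  set.seed(19)
  K <- 12; M <- 30
  hap <- matrix(rbinom(K * M, 1, 0.4), K, M)
  emis <- matrix(runif(M * 3), M, 3)
  gmap <- runif(M - 1, 0.01, 0.5)
  a <- forward_backward(emis, hap, gmap)$posterior
  b <- forward_backward(emis, hap[sample(K), ], gmap)$posterior
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("a uniform-emission site is transparent to its neighbours", {
  set.seed(23)
  K <- 3
  hap3 <- matrix(rbinom(K * 3, 1, 0.5), K, 3)
  emis3 <- rbind(runif(3), c(1, 1, 1), runif(3))
  d <- c(0.3, 0.5)
  p3 <- forward_backward(emis3, hap3, d)$posterior
  # dropping the uninformative middle site (distances add along the map)
  p2 <- forward_backward(emis3[c(1, 3), ], hap3[, c(1, 3)], sum(d))$posterior
  expect_lt(max(abs(p3[c(1, 3), ] - p2)), 1e-10)
})

test_that("emission validation catches degenerate inputs", {
  hap <- matrix(0L, 2, 2)
  emis <- rbind(c(1, 1, 1), c(0, 0, 0))
  expect_error(forward_backward(emis, hap, 0.1), "site 2")
  expect_error(forward_backward(matrix(1, 1, 3), hap, numeric(0)),
               "n_sites")
})

test_that("stage 1 calls a sharply observed genotype with panel support", {
  pan <- small_panel()$panel
  gl_sample <- list(sample_id = "X", covered = c(10L, 11L),
                    lik = rbind(c(1e-6, 1e-3, 1), c(1e-6, 1e-3, 1)),
                    error_rate = 0.005)
  # plant a panel pair that is hom-alt at the covered sites
  pan$haplotypes[1:2, 10:11] <- 1L
  sim <- stats::setNames(rep(0.5, length(pan$sample_ids)), pan$sample_ids)
  custom <- select_custom_panel(sim, pan, "X", panel_size = 20L)
  s1 <- impute_stage1(gl_sample, custom, pan)
  expect_gt(s1$posterior[1, 3], 0.99)
  expect_equal(rowSums(s1$posterior), rep(1, 2), tolerance = 1e-8)
  expect_error(impute_stage1(list(sample_id = "X", covered = integer(0),
                                  lik = matrix(0, 0, 3)), custom, pan),
               "zero covered")
})

test_that("stage-1 posterior beats the naive GL argmax at 0.5x", {
  pan <- small_panel()$panel
  tg <- generate_targets(pan, 6L, seed = 55L)
  pl <- simulate_pileups(tg$truth, 0.5, seed = 56L)
  gls <- compute_gl(pl)
  conc_hmm <- conc_naive <- numeric(0)
  for (i in seq_len(6)) {
    gs <- gls$samples[[i]]
    d0 <- rep(NA_real_, nrow(pan$sites))
    d0[gs$covered] <- (gs$lik[, 2] + 2 * gs$lik[, 3]) / rowSums(gs$lik)
    depth <- pl$n_ref[i, ] + pl$n_alt[i, ]
    comp <- order(depth, seq_along(depth), decreasing = TRUE)[1:60]
    sim <- ibs_similarity(d0, pan, comp)
    custom <- select_custom_panel(sim, pan, gs$sample_id, panel_size = 60L)
    s1 <- impute_stage1(gs, custom, pan)
    truth_cov <- tg$truth$genotypes[i, gs$covered]
    conc_hmm <- c(conc_hmm, mean(max.col(s1$posterior) - 1L == truth_cov))
    conc_naive <- c(conc_naive, mean(max.col(gs$lik) - 1L == truth_cov))
  }
  expect_gt(mean(conc_hmm), mean(conc_naive))
})

test_that("stage 2 interpolates an uncovered site from confident flanks", {
  # 3-site panel; only haplotype 1 is alt at both flanks, so a target that is
  # confidently hom-alt at sites 1 and 3 must copy the pair (1, 1)
  hap <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 0L))
  pan <- structure(list(
    sites = data.frame(chrom = "chrS", pos = c(100L, 200L, 300L),
                       ref = "A", alt = "G"),
    haplotypes = hap, sample_ids = c("P1", "P2"),
    population_of = stats::setNames(c("P", "P"), c("P1", "P2")),
    genetic_map = c(0.001, 0.001), cum_cm = c(0, 0.001, 0.002),
    pedigree = list(P1 = NULL, P2 = NULL), config = NULL),
    class = "haplotype_panel")
  s1 <- list(sample_id = "X", covered = c(1L, 3L),
             posterior = rbind(c(1e-8, 1e-4, 1), c(1e-8, 1e-4, 1)))
  s2 <- impute_stage2(s1, pan, hmm_params(lambda = 1e-6))
  # haplotype pair (hap1, hap1) is hom-alt at site 2 as well
  expect_lt(abs(s2$dosage[2] - 2), 0.05)
  expect_true(all(s2$dosage >= 0 & s2$dosage <= 2))
})

test_that("single-pass and two-stage pipelines agree on dosages", {
  pan <- small_panel()$panel
  tg <- generate_targets(pan, 8L, seed = 71L)
  pl <- simulate_pileups(tg$truth, 0.5, seed = 72L)
  two <- impute_cohort(pl, pan, panel_size = 60L)
  one <- impute_single_pass(pl, pan)
  expect_true(all(two$dosage >= 0 & two$dosage <= 2))
  expect_lt(mean(abs(two$dosage - one$dosage)), 0.05)
})
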