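test_that("array simulation reproduces truth when noise-free", {
  pan <- small_panel()$panel
  truth <- small_panel()$truth
  arr <- simulate_array(truth, pan, typed_fraction = 0.5, miss_rate = 0,
                        geno_error = 0, seed = 3L)
  expect_identical(arr$genotypes,
                   truth$genotypes[, arr$typed, drop = FALSE],
                   ignore_attr = TRUE)

  arr_all <- simulate_array(truth, pan, typed_fraction = 1, miss_rate = 0,
                            geno_error = 0, seed = 3L)
  expect_identical(arr_all$typed, seq_len(nrow(pan$sites)))

  # no ascertainment weight: typed-site MAF distribution matches the panel's
  arr0 <- simulate_array(truth, pan, typed_fraction = 0.5,
                         ascertainment_weight = 0, seed = 4L)
  ks0 <- suppressWarnings(stats::ks.test(arr0$sites$maf, pan$sites$maf))
  expect_gt(ks0$p.value, 0.01)
  # positive weight enriches common variants
  arr1 <- simulate_array(truth, pan, typed_fraction = 0.3,
                         ascertainment_weight = 2, seed = 4L)
  expect_gt(mean(arr1$sites$maf), mean(pan$sites$maf))
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)   # monomorphic
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)   # modal outcome, both terms sum
  # spot tables vs exhaustive allele-placement enumeration
  for (tab in list(c(1, 2, 1), c(3, 1, 1), c(0, 4, 0), c(2, 0, 2),
                   c(4, 1, 0), c(1, 1, 3))) {
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 hwe_enumeration_oracle(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12,
                 label = paste("table", paste(tab, collapse = "/")))
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 1, 0), "nonnegative")
  # large-count stability: p stays in (0, 1]
  p <- hwe_exact_test(5000, 3000, 2000)
  expect_true(p > 0 && p <= 1)
})

test_that("array QC filters act in order with a hand-counted fixture", {
  # 10 sites: 2 ambiguous (A/T, C/G), 1 with 10% missingness, rest clean
  n <- 40L
  set.seed(90)
  G <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  G[1:4, 3] <- NA          # site 3: 10% missing
  sites <- data.frame(chrom = "chrS", pos = 1:10 * 100L,
                      ref = c("A", "C", "G", "A", "C", "G", "T", "A", "C", "G"),
                      alt = c("C", "G", "A", "T", "A", "T", "C", "G", "T", "A"),
                      stringsAsFactors = FALSE)
  # ambiguous pairs: site 2 (C/G) and site 4 (A/T)
  arr <- structure(list(typed = 1:10, genotypes = G, sites = sites,
                        missingness = colMeans(is.na(G)),
                        call_rate = rowMeans(!is.na(G)),
                        sample_ids = sprintf("S%02d", 1:n), seed = 1L),
                   class = "array_genotypes")
  qc <- array_qc(arr, miss_threshold = 0.05, hwe_alpha = 1e-12)
  expect_equal(ncol(qc$array$genotypes), 7L)
  rep <- qc$report
  expect_equal(rep$removed[rep$filter == "missingness"], 1L)
  expect_equal(rep$removed[rep$filter == "ambiguous_strand"], 2L)
  expect_equal(rep$removed[rep$filter == "hwe"], 0L)

  # thresholds disabled: only the ambiguous-strand filter acts
  qc2 <- array_qc(arr, miss_threshold = 1.0, hwe_alpha = 0)
  expect_equal(ncol(qc2$array$genotypes), 8L)

  # a sample with call rate just below 97% is excluded
  G3 <- matrix(rbinom(n * 100, 2, 0.4), n, 100)
  G3[1, 1:4] <- NA         # call rate 0.96
  sites3 <- data.frame(chrom = "chrS", pos = 1:100 * 10L, ref = "A", alt = "C",
                       stringsAsFactors = FALSE)
  arr3 <- structure(list(typed = 1:100, genotypes = G3, sites = sites3,
                         missingness = colMeans(is.na(G3)),
                         call_rate = rowMeans(!is.na(G3)),
                         sample_ids = sprintf("S%02d", 1:n), seed = 1L),
                    class = "array_genotypes")
  qc3 <- array_qc(arr3, miss_threshold = 0.5, hwe_alpha = 0)
  expect_false("S01" %in% qc3$array$sample_ids)
  expect_equal(qc3$report$removed[qc3$report$filter == "sample_call_rate"], 1L)
})

test_that("array-based imputation reproduces typed genotypes and stays bounded", {
  pan <- small_panel()$panel
  tg <- generate_targets(pan, 4L, seed = 61L)
  arr <- simulate_array(tg$truth, pan, typed_fraction = 1, miss_rate = 0,
                        geno_error = 0, seed = 62L)
  dm <- impute_from_array(arr, pan, epsilon = 1e-4)
  expect_true(all(dm$dosage >= 0 & dm$dosage <= 2))
  expect_lt(max(abs(dm$dosage - tg$truth$genotypes)), 0.05)
})

test_that("array-arm and lcWGS-arm imputation agree at untyped sites", {
  pan <- small_panel()$panel
  tg <- generate_targets(pan, 6L, seed = 81L)
  arr <- simulate_array(tg$truth, pan, typed_fraction = 0.25, miss_rate = 0.01,
                        geno_error = 0.002, seed = 82L)
  dm_arr <- impute_from_array(array_qc(arr)$array, pan)
  pl <- simulate_pileups(tg$truth, 1.0, seed = 83L)
  dm_lc <- impute_cohort(pl, pan, panel_size = 60L)
  untyped <- setdiff(seq_len(nrow(pan$sites)), arr$typed)
  r2_of <- function(dm) {
    ps <- dosage_r2(dm, tg$truth, "per_site")
    mean(ps$r2[untyped], na.rm = TRUE)
  }
  r2a <- r2_of(dm_arr); r2l <- r2_of(dm_lc)
  expect_gt(r2a, 0.8)
  expect_gt(r2l, 0.8)
})
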