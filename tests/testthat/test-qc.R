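
test_that("sample call statistics recover planted inbreeding structure", {
  ## fully homozygous sample: numerator equals denominator, F = 1
  g <- rbind(rep(c(0L, 2L), 10), rep(1L, 20), rbinom(20, 2, 0.5))
  x <- toy_matrix(g)
  st <- sample_call_stats(x)
  expect_equal(st$f[1], 1)

  ## all-heterozygous sample: plug-in expected-homozygosity formula
  af <- allele_freq(x)
  het_corr <- 2 * af$p_alt * (1 - af$p_alt) * af$n_alleles /
    (af$n_alleles - 1)
  expect_equal(st$exp_hom[2], sum(1 - het_corr))
  expect_equal(st$f[2], (0 - st$exp_hom[2]) / (20 - st$exp_hom[2]))
  expect_lt(st$f[2], -0.8)

  expect_error(sample_call_stats(x[1, ]), "2 samples")
})

test_that("mean F is near zero in a Hardy-Weinberg cohort", {
  sim <- hwe_cohort()
  st <- sample_call_stats(sim$matrix)
  expect_lt(abs(mean(st$f)), 0.02)
})

test_that("the exact HWE test matches full enumeration up to n = 50", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(5, 0, 0), 1)

  set.seed(1)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    counts <- as.vector(rmultinom(1, n, prob = runif(3)))
    ora <- hwe_oracle(counts[1], counts[2], counts[3])
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]), ora$p,
                 tolerance = 1e-12)
    expect_equal(sum(ora$probs), 1, tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 0, 1), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("site filters apply in order and ledger every removal", {
  ## 10 loci, one planted failure per filter
  set.seed(2)
  n <- 30
  g <- matrix(1L, n, 10)
  for (j in 1:10) g[, j] <- rbinom(n, 2, 0.4)
  g[1:3, 1] <- NA              # locus 1: 10% missing > 5%
  g[, 2] <- 1L                 # locus 2: all het, extreme HWE departure
  g[, 3] <- 0L; g[1, 3] <- 1L  # locus 3: MAF = 1/60 < 0.05
  x <- toy_matrix(g)
  expect_lt(hwe_exact_test(0, n, 0), 1e-5)
  res <- filter_sites(x, qc_config())
  expect_equal(res$report$removed, c(1, 1, 1))
  expect_equal(res$report$retained, c(9, 8, 7))
  expect_equal(n_loci(res$matrix), 7L)
  expect_false(any(c("chr01_1000", "chr01_2000", "chr01_3000") %in%
                     res$matrix$loci$id))

  ## fully permissive thresholds change nothing
  res0 <- filter_sites(x, qc_config(geno = 1, hwe_p = 0, maf_min = 0))
  expect_equal(n_loci(res0$matrix), 10L)
  expect_equal(res0$report$removed, c(0, 0, 0))
})

test_that("sample missingness filter is strict and reports removals", {
  g <- matrix(0L, 5, 20)
  g[1, 1:11] <- NA   # 55% missing
  g[2, 1:4] <- NA    # exactly 20%: retained under strict '>'
  x <- toy_matrix(g)
  res <- filter_samples(x, qc_config(mind = 0.2))
  expect_equal(res$removed$sample, "S01")
  expect_equal(res$removed$missing_rate, 0.55)
  expect_equal(n_samples(res$matrix), 4L)
  expect_equal(attrition_retained(res$report), 4)

  none <- filter_samples(toy_matrix(matrix(1L, 3, 5)), qc_config())
  expect_equal(n_samples(none$matrix), 3L)
})

test_that("ld_r2 is the squared dosage correlation over complete pairs", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)

  ## hand oracle via explicit sums
  a <- c(0, 0, 1, 2, 2)
  b <- c(0, 1, 1, 1, 2)
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  oracle <- sxy^2 / (sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(ld_r2(a, b), oracle)
  expect_equal(oracle, 0.5)

  expect_true(is.nan(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.nan(ld_r2(c(0, NA, 2), c(0, 1, NA))))
})


test_that("windowed LD pruning matches the brute-force rule", {
  ## mutually independent loci are untouched
  set.seed(3)
  g <- matrix(rbinom(40 * 8, 2, 0.5), 40, 8)
  x <- toy_matrix(g)
  res <- ld_prune(x, window = 50, step = 5, r2_max = 0.5)
  expect_true(all(res$keep))

  ## two perfectly correlated adjacent loci: exactly one survives
  g2 <- cbind(g[, 1], g[, 1], g[, 3:8])
  x2 <- toy_matrix(g2)
  res2 <- ld_prune(x2, window = 50, step = 5, r2_max = 0.5)
  expect_equal(sum(!res2$keep), 1L)
  expect_equal(sum(res2$keep[1:2]), 1L)

  ## 10-locus fixture with correlation blocks vs the oracle
  set.seed(9)
  base <- rbinom(60, 2, 0.5)
  g3 <- cbind(base,
              ifelse(runif(60) < 0.9, base, rbinom(60, 2, 0.5)),
              ifelse(runif(60) < 0.8, base, rbinom(60, 2, 0.3)),
              matrix(rbinom(60 * 5, 2, runif(5, 0.2, 0.5)), 60, 5),
              2 - base, rbinom(60, 2, 0.25))
  x3 <- toy_matrix(g3)
  res3 <- ld_prune(x3, window = 10, step = 5, r2_max = 0.5)
  expect_equal(which(res3$keep), prune_oracle(x3, 0.5))

  ## post-condition: no surviving within-window pair above the ceiling
  sim <- hwe_cohort()
  xs <- sim$matrix[, 1:500]
  rs <- ld_prune(xs, window = 20, step = 5, r2_max = 0.5)
  kept <- which(rs$keep)
  for (s in seq(1, length(kept) - 19, by = 5)) {
    win <- kept[s:min(s + 19, length(kept))]
    r2 <- suppressWarnings(cor(xs$dosage[, win],
                               use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.5)
  }
})

test_that("single-pass F-outlier screen flags only true outliers", {
  sim <- hwe_cohort()
  inj <- inject_defects(sim$matrix,
                        defect_spec(high_missing = numeric(0),
                                    duplicate = FALSE),
                        seed = 6)
  st <- sample_call_stats(inj$matrix)
  flagged <- detect_het_outliers(st, f_sd = 3)
  expect_setequal(flagged, inj$labels$sample)

  same <- toy_matrix(matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4))
  st_same <- sample_call_stats(same)
  expect_length(detect_het_outliers(st_same, 3), 0L)
  expect_error(detect_het_outliers(st_same[1:2, ], 3), "at least 3")
})

test_that("HWE filter at 1e-5 removes almost nothing under the null", {
  sim <- cached("hwe20k", function() {
    m <- cohort_model(n_samples = 60, n_pops = 1, divergence = 1e-4,
                      alpha = 1, chrom_lengths = rep(2e6, 10),
                      snp_spacing = 1000, ld_scale = 1,
                      segment_mean_loci = 1, site_missing_rate = 0,
                      sample_missing_rate = 0, seed = 77)
    simulate_cohort(m)
  })
  p <- germprint:::hwe_test_matrix(sim$matrix)
  ## 20,000 truly neutral loci at alpha = 1e-5: Poisson(0.2) upper bound
  expect_lte(sum(p < 1e-5), 3)
})

test_that("relatedness screen separates duplicates from the unrelated", {
  set.seed(4)
  g <- matrix(rbinom(30 * 400, 2, runif(400, 0.1, 0.9)), 30, 400,
              byrow = FALSE)
  g <- rbind(g, g[1, ])  # exact duplicate of sample 1
  x <- toy_matrix(g)
  rel <- relatedness_screen(x, qc_config())
  ids <- sample_ids(x)
  dup_row <- rel[rel$sample_a == ids[1] & rel$sample_b == ids[31], ]
  expect_equal(dup_row$ibs, 1)
  expect_gt(dup_row$pi_hat, 0.98)
  expect_true(dup_row$flagged)

  ## opposite homozygotes share nothing
  y <- toy_matrix(rbind(rep(0L, 200), rep(2L, 200), rbinom(200, 2, 0.5)))
  rel_y <- relatedness_screen(y, qc_config())
  expect_equal(rel_y$ibs[rel_y$sample_a == "S01" & rel_y$sample_b == "S02"],
               0)

  ## short overlap is reported low-confidence, never flagged
  z <- toy_matrix(rbind(c(rep(0L, 10), rep(NA, 90)),
                        c(rep(0L, 10), rep(NA, 90)),
                        rbinom(100, 2, .5)))
  rel_z <- relatedness_screen(z, qc_config())
  lowc <- rel_z[rel_z$sample_a == "S01" & rel_z$sample_b == "S02", ]
  expect_true(lowc$low_confidence)
  expect_false(lowc$flagged)
})

test_that("PI_HAT is near zero for unrelated samples", {
  sim <- hwe_cohort()
  rel <- relatedness_screen(sim$matrix, qc_config())
  expect_lt(abs(mean(rel$pi_hat)), 0.05)
  expect_false(any(rel$flagged))
})
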