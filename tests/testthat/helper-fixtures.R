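# Shared fixtures, built in code. Simulated cohorts are cached per test
# file run so several tests can reuse one draw.

toy_loci <- function(n, chrom = "chr01", start = 1000L, by = 1000L,
                     ref = "A", alt = "G") {
  pos <- seq(start, by = by, length.out = n)
  data.frame(chrom = chrom, pos = pos, id = paste0(chrom, "_", pos),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

toy_matrix <- function(dosage, chrom = "chr01") {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, toy_loci(ncol(dosage), chrom = chrom))
}

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- maker()
  .cohort_cache[[key]]
}

# Panmictic (K = 1) cohort with effectively unlinked loci: genotypes are
# Binomial(2, p_anc) draws.
hwe_cohort <- function(n_loci = 10000, n = 60, seed = 42) {
  cached(sprintf("hwe_%d_%d_%d", n_loci, n, seed), function() {
    m <- cohort_model(n_samples = n, n_pops = 1, divergence = 1e-4,
                      alpha = 1, chrom_lengths = rep(n_loci * 1000 / 10, 10),
                      snp_spacing = 1000, ld_scale = 1,
                      segment_mean_loci = 1, site_missing_rate = 0,
                      sample_missing_rate = 0, seed = seed)
    simulate_cohort(m)
  })
}

# Three-population admixed cohort matching the generator defaults but at
# desk scale (unlinked loci).
admixed_cohort <- function(n_loci = 5000, n = 60, seed = 1) {
  cached(sprintf("adm_%d_%d_%d", n_loci, n, seed), function() {
    m <- cohort_model(n_samples = n, chrom_lengths = rep(n_loci * 250, 20),
                      snp_spacing = 5000, ld_scale = 1,
                      segment_mean_loci = 1, seed = seed)
    simulate_cohort(m)
  })
}

# All six label permutations for K = 3 Q-matrix comparisons.
perms3 <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
               c(3, 2, 1))

q_rmse <- function(Q, Q_true) {
  min(vapply(perms3, function(p) sqrt(mean((Q[, p] - Q_true)^2)), 0))
}
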