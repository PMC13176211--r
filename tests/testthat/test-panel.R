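
test_that("probability of identity matches direct evaluation", {
  o <- poi_oracle(0.5)
  expect_equal(o$pi, 0.375)
  expect_equal(o$sib, 0.59375)
  r <- probability_of_identity(0.5)
  expect_equal(r$pi, 0.375)
  expect_equal(r$pi_sibs, 0.59375)

  ## empty panel: empty products
  r0 <- probability_of_identity(numeric(0))
  expect_equal(r0$pi, 1)
  expect_equal(r0$pi_sibs, 1)

  ## fixed locus contributes 1 with a warning
  expect_warning(rf <- probability_of_identity(c(0.5, 1)), "fixed")
  expect_equal(rf$pi, 0.375)

  ## log-space product equals the direct product on small panels
  set.seed(12)
  p <- runif(20, 0.05, 0.95)
  r20 <- probability_of_identity(p)
  direct <- prod(vapply(p, function(pp) poi_oracle(pp)$pi, 0))
  direct_s <- prod(vapply(p, function(pp) poi_oracle(pp)$sib, 0))
  expect_equal(r20$pi, direct, tolerance = 1e-10)
  expect_equal(r20$pi_sibs, direct_s, tolerance = 1e-10)
  expect_true(r20$pi <= r20$pi_sibs)

  ## adding any locus strictly decreases both products
  r21 <- probability_of_identity(c(p, 0.3))
  expect_lt(r21$pi, r20$pi)
  expect_lt(r21$pi_sibs, r20$pi_sibs)

  expect_error(probability_of_identity(c(0.2, 1.4)), "\\[0, 1\\]")
})

# A dense candidate matrix where every locus passes the marginal
# filters: hets and homs balanced, no missingness.
dense_candidates <- function(n, loci_per_chrom, n_chrom, spacing = 2e6,
                             seed = 31) {
  set.seed(seed)
  L <- loci_per_chrom * n_chrom
  p <- runif(L, 0.35, 0.5)
  g <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  ## guarantee observed hets above 0.30 at every locus
  for (j in which(colMeans(g == 1) <= 0.32)) {
    need <- ceiling(0.35 * n) - sum(g[, j] == 1)
    if (need > 0) {
      hom <- which(g[, j] != 1)
      g[hom[seq_len(min(need, length(hom)))], j] <- 1L
    }
  }
  chrom <- rep(sprintf("c%02d", seq_len(n_chrom)), each = loci_per_chrom)
  pos <- rep(seq(spacing, by = spacing, length.out = loci_per_chrom),
             n_chrom)
  loci <- data.frame(chrom = chrom, pos = pos,
                     id = paste0(chrom, "_", pos), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  genotype_matrix(g, loci, samples = sprintf("S%02d", seq_len(n)))
}

test_that("a feasible pool is selected in full with even quotas", {
  x <- dense_candidates(40, loci_per_chrom = 10, n_chrom = 4)
  st <- locus_diversity(x, hwe = FALSE)
  cfg <- panel_config(size_target = 40, min_spacing_bp = 1e6, r2_max = 1)
  spec <- select_panel(x, st, cfg)
  expect_equal(nrow(spec$loci), 40L)
  expect_false(spec$shortfall)
  expect_equal(as.vector(spec$per_chrom), rep(10L, 4))
  ## everything selected passes the marginal filters
  expect_true(all(spec$loci$maf > 0.25 & spec$loci$pic > 0.25 &
                    spec$loci$ho > 0.30))
})

test_that("quota redistribution handles chromosomes without candidates", {
  x <- dense_candidates(40, loci_per_chrom = 12, n_chrom = 2)
  ## kill every candidate on chromosome 2 via MAF
  g <- x$dosage
  g[, x$loci$chrom == "c02"] <- 0L
  g[1, x$loci$chrom == "c02"] <- 1L
  x2 <- genotype_matrix(g, x$loci, samples = sample_ids(x))
  st <- locus_diversity(x2, hwe = FALSE)
  cfg <- panel_config(size_target = 16, min_spacing_bp = 1e6, r2_max = 1)
  spec <- select_panel(x2, st, cfg)
  expect_equal(as.vector(spec$per_chrom), c(12L, 0L))
  expect_true(spec$shortfall)  # only 12 of 16 available
})

# Exhaustive oracle: best per-chromosome quota-sized subsets maximising
# total PIC subject to the pairwise r2 and spacing constraints.
panel_oracle <- function(x, st, cfg, quota) {
  G <- x$dosage
  best <- list(pic = -Inf, sel = NULL)
  cand <- lapply(unique(x$loci$chrom), function(ch)
    which(x$loci$chrom == ch & st$maf > cfg$maf_min & st$pic > cfg$pic_min &
            st$ho > cfg$het_min & (1 - st$call_rate) <= cfg$max_missing))
  pick <- function(ci, chosen) {
    if (ci > length(cand)) {
      tot <- sum(st$pic[chosen])
      if (tot > best$pic) best <<- list(pic = tot, sel = sort(chosen))
      return(invisible())
    }
    for (comb in combn(cand[[ci]], min(quota, length(cand[[ci]])),
                       simplify = FALSE)) {
      ok <- TRUE
      for (a in seq_along(comb)) {
        for (b in seq_len(a - 1L)) {
          r2 <- ld_r2(G[, comb[a]], G[, comb[b]])
          if ((!is.nan(r2) && r2 >= cfg$r2_max) ||
              abs(x$loci$pos[comb[a]] - x$loci$pos[comb[b]]) <
                cfg$min_spacing_bp) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) pick(ci + 1L, c(chosen, comb))
    }
  }
  pick(1L, integer(0))
  best
}

test_that("greedy selection matches the exhaustive oracle on a fixture", {
  x <- dense_candidates(50, loci_per_chrom = 8, n_chrom = 2, seed = 41)
  ## plant one perfectly linked, maximally informative pair on
  ## chromosome 1, so both rank first on PIC and the r2 constraint must
  ## break the tie
  g <- x$dosage
  g[, 1] <- rep(c(0L, 1L, 2L, 1L), length.out = nrow(g))
  g[, 2] <- g[, 1]
  x <- genotype_matrix(g, x$loci, samples = sample_ids(x))
  st <- locus_diversity(x, hwe = FALSE)
  cfg <- panel_config(size_target = 6, min_spacing_bp = 1e6, r2_max = 0.2)
  spec <- select_panel(x, st, cfg)
  sel <- match(spec$loci$id, x$loci$id)

  ## exactly one member of the linked pair survives
  expect_equal(sum(sel %in% 1:2), 1L)
  ## no selected same-chromosome pair violates r2 or spacing
  for (a in seq_along(sel)) for (b in seq_len(a - 1L)) {
    if (x$loci$chrom[sel[a]] == x$loci$chrom[sel[b]]) {
      r2 <- ld_r2(g[, sel[a]], g[, sel[b]])
      expect_true(is.nan(r2) || r2 < 0.2)
      expect_gte(abs(x$loci$pos[sel[a]] - x$loci$pos[sel[b]]), 1e6)
    }
  }
  ## greedy total PIC reaches at least 95% of the exhaustive optimum
  oracle <- panel_oracle(x, st, cfg, quota = 3)
  expect_gte(sum(st$pic[sel]), 0.95 * oracle$pic)
})

test_that("panel metrics summarise the selected loci", {
  x <- dense_candidates(30, loci_per_chrom = 6, n_chrom = 3)
  st <- locus_diversity(x, hwe = FALSE)
  spec <- select_panel(x, st, panel_config(size_target = 12,
                                           min_spacing_bp = 1e6,
                                           r2_max = 1))
  pm <- panel_metrics(x, spec)
  expect_equal(pm$n_loci, 12)
  expect_true(pm$pic_mean > 0.25 && pm$pic_mean <= 0.375)
  expect_equal(pm$pi,
               probability_of_identity(
                 allele_freq(x[, spec$loci$id])$p_alt)$pi)
  expect_true(pm$pi <= pm$pi_sibs)
})

test_that("uniqueness check flags only true duplicate profiles", {
  x <- dense_candidates(20, loci_per_chrom = 10, n_chrom = 2)
  st <- locus_diversity(x, hwe = FALSE)
  spec <- select_panel(x, st, panel_config(size_target = 20,
                                           min_spacing_bp = 1e6,
                                           r2_max = 1))
  ## plant an exact duplicate
  g <- rbind(x$dosage, x$dosage[3, ])
  rownames(g)[21] <- "DUP"
  xd <- genotype_matrix(g, x$loci, samples = rownames(g))
  uq <- uniqueness_check(xd, spec, min_overlap = 10)
  expect_false(uq$distinct)
  expect_true(any(uq$conflicts$sample_b == "DUP"))

  ## one flip makes the pair distinguishable again
  g2 <- g
  g2[21, 1] <- if (g2[21, 1] == 0L) 2L else 0L
  uq2 <- uniqueness_check(genotype_matrix(g2, x$loci,
                                          samples = rownames(g2)),
                          spec, min_overlap = 10)
  expect_false(any(uq2$conflicts$sample_b == "DUP"))

  ## an all-missing sample has insufficient overlap everywhere
  g3 <- g
  g3[21, ] <- NA_integer_
  uq3 <- uniqueness_check(genotype_matrix(g3, x$loci,
                                          samples = rownames(g3)),
                          spec, min_overlap = 10)
  expect_true(all(uq3$insufficient$n_overlap == 0))
  expect_true(uq3$distinct)
})

test_that("fingerprints encode IUPAC genotypes with a valid checksum", {
  g <- matrix(c(0L, 1L, 2L, NA, 0L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  loci <- data.frame(chrom = "c01", pos = c(10L, 20L, 30L),
                     id = c("l1", "l2", "l3"),
                     ref = c("A", "A", "G"), alt = c("G", "G", "T"),
                     stringsAsFactors = FALSE)
  x <- genotype_matrix(g, loci)
  spec <- structure(list(loci = cbind(loci, maf = .5, ho = .5, he = .5,
                                      pic = .375, call_rate = 1),
                         per_chrom = table("c01"),
                         constraints = NULL, shortfall = FALSE,
                         config = panel_config(size_target = 3)),
                    class = "panel_spec")
  fa <- encode_fingerprint(x, spec, "a")
  expect_equal(fa$genotype, "ART")   # hom ref, het A/G, hom alt
  fb <- encode_fingerprint(x, spec, "b")
  expect_equal(fb$genotype, "NAK")   # missing, hom ref, het G/T

  dec <- decode_fingerprint(fa$payload)
  expect_equal(dec$sample, "a")
  expect_equal(dec$genotype, fa$genotype)
  expect_equal(dec$panel_hash, fa$panel_hash)

  ## a single corrupted character breaks the checksum
  bad <- sub("ART", "AGT", fa$payload, fixed = TRUE)
  expect_error(decode_fingerprint(bad), "checksum")
  expect_error(encode_fingerprint(x, spec, "zzz"), "not found")
  expect_error(decode_fingerprint("GP2|x|y|z|00000000"), "payload")
})

test_that("random fingerprints roundtrip through encode/decode", {
  x <- dense_candidates(10, loci_per_chrom = 15, n_chrom = 1)
  st <- locus_diversity(x, hwe = FALSE)
  spec <- select_panel(x, st, panel_config(size_target = 15,
                                           min_spacing_bp = 1e6,
                                           r2_max = 1))
  for (s in sample_ids(x)) {
    fp <- encode_fingerprint(x, spec, s)
    dec <- decode_fingerprint(fp$payload)
    expect_identical(dec$genotype, fp$genotype)
    expect_identical(dec$sample, s)
  }
})

test_that("150 informative loci keep 64-sample profiles distinct across
           100 seeded replicates", {
  ## The computed per-locus PI bounds the collision probability: at
  ## MAF > 0.25 a 150-locus panel has PI below ~0.6^150, so no
  ## collision should ever be observed among 64 samples.
  collisions <- 0L
  for (s in 1:100) {
    m <- cohort_model(n_samples = 64, n_pops = 1, divergence = 1e-4,
                      chrom_lengths = 150e3, snp_spacing = 1000,
                      ld_scale = 1, segment_mean_loci = 1,
                      ancestral_maf_law = function(n) runif(n, 0.3, 0.7),
                      site_missing_rate = 0, sample_missing_rate = 0,
                      seed = s)
    x <- simulate_cohort(m)$matrix
    st <- locus_diversity(x, hwe = FALSE)
    spec <- select_panel(x, st,
                         panel_config(size_target = 150, maf_min = 0.25,
                                      pic_min = 0, het_min = 0,
                                      r2_max = 1, min_spacing_bp = 0))
    uq <- uniqueness_check(x, spec, min_overlap = 50)
    collisions <- collisions + nrow(uq$conflicts)
  }
  expect_identical(collisions, 0L)
})
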