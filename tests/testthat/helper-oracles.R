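# Independent oracle implementations used to cross-check the package.
# Each is written directly from first principles and shares no code with
# the implementation it checks.

# Exact HWE probabilities by direct enumeration of every genotype
# configuration compatible with the observed allele counts (multinomial
# coefficient times 2^het, normalised).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(list(p = 1, probs = 1))
  hets <- seq(0, n)
  keep <- (nA - hets) %% 2 == 0 & hets <= nA & hets <= 2 * n - nA &
    (n - hets - (nA - hets) / 2) >= 0
  hets <- hets[keep]
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - h - aa
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  list(p = sum(pr[pr <= obs * (1 + 1e-9)]), probs = pr)
}

# Scalar Weir-Cockerham (1984) variance components for two populations
# at one locus, written from the component definitions.
wc_oracle_locus <- function(g1, g2) {
  r <- 2
  n_i <- c(length(g1), length(g2))
  p_i <- c(mean(g1) / 2, mean(g2) / 2)
  h_i <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Brute-force mirror of the pruning rule on one window covering all
# loci: repeatedly locate the highest-r2 offending pair (ties by index
# order) and drop its lower-MAF member (ties: later locus).
prune_oracle <- function(x, r2_max) {
  G <- x$dosage
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  kept <- seq_len(ncol(G))
  repeat {
    best <- NULL
    for (ai in seq_along(kept)) for (bi in seq_len(ai - 1L)) {
      r2 <- ld_r2(G[, kept[bi]], G[, kept[ai]])
      if (!is.nan(r2) && r2 > r2_max &&
          (is.null(best) || r2 > best$r2 + 1e-12))
        best <- list(a = kept[bi], b = kept[ai], r2 = r2)
    }
    if (is.null(best)) break
    drop <- if (maf[best$a] < maf[best$b]) best$a
            else if (maf[best$b] < maf[best$a]) best$b
            else max(best$a, best$b)
    kept <- setdiff(kept, drop)
  }
  kept
}

# Direct longhand evaluation of the identity formulas for one locus.
poi_oracle <- function(p) {
  q <- 1 - p
  list(pi = p^4 + q^4 + (2 * p * q)^2,
       sib = 0.25 + 0.5 * (p^2 + q^2) + 0.5 * (p^2 + q^2)^2 -
         0.25 * (p^4 + q^4))
}
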