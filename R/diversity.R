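#' Polymorphic information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`; bounded by
#' 0.375, attained at `p = 0.5`.
#'
#' @param p allele frequency (vectorised).
#' @return PIC values in `[0, 0.375]`.
#' @export
pic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Expected heterozygosity of a biallelic locus
#'
#' Plug-in `He = 2 p (1 - p)` (no small-sample correction; the
#' nucleotide-diversity estimator carries the `2n/(2n-1)` correction
#' explicitly).
#'
#' @param p allele frequency (vectorised).
#' @return He values in `[0, 0.5]`.
#' @export
expected_het <- function(p) 2 * p * (1 - p)

#' Per-locus diversity statistics
#'
#' @param x a [genotype_matrix()].
#' @param hwe logical; also compute the exact Hardy-Weinberg p-value per
#'   locus (exact enumeration; set `FALSE` to skip on very large
#'   matrices).
#' @return data.frame with one row per locus: `id`, `chrom`, `pos`,
#'   `n_alleles` (called allele count), `call_rate`, `p_alt`, `maf`,
#'   `ho` (observed heterozygote fraction), `he` (plug-in expected
#'   heterozygosity), `pic`, `hwe_p`, `pi_site` (per-site nucleotide
#'   diversity `2 p q n/(n-1)` with `n` the called allele count).
#'   Monomorphic loci get `maf = he = pic = pi_site = 0`; loci with
#'   fewer than 2 called alleles get `NA` statistics.
#' @export
locus_diversity <- function(x, hwe = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  G <- x$dosage
  af <- allele_freq(x)
  n_al <- af$n_alleles
  p <- af$p_alt
  usable <- n_al >= 2L
  maf <- pmin(p, 1 - p)
  he <- expected_het(p)
  pic_v <- pic(p)
  pi_site <- he * n_al / pmax(n_al - 1L, 1L)
  n_called <- n_al / 2
  ho <- colSums(G == 1L, na.rm = TRUE) / pmax(n_called, 1)
  maf[!usable] <- he[!usable] <- pic_v[!usable] <- pi_site[!usable] <-
    ho[!usable] <- NA_real_
  hwe_p <- if (hwe) hwe_test_matrix(x) else rep(NA_real_, n_loci(x))
  hwe_p[!usable] <- NA_real_
  data.frame(id = x$loci$id, chrom = x$loci$chrom, pos = x$loci$pos,
             n_alleles = n_al, call_rate = n_called / n_samples(x),
             p_alt = p, maf = maf, ho = ho, he = he, pic = pic_v,
             hwe_p = hwe_p, pi_site = pi_site, stringsAsFactors = FALSE)
}

#' Cohort-wide means of the per-locus statistics
#'
#' @param stats data.frame from [locus_diversity()].
#' @return one-row data.frame with `n_loci`, `mean_maf`, `mean_pic`,
#'   `mean_he`, `mean_ho`, `mean_call_rate`.
#' @export
cohort_summary <- function(stats) {
  if (nrow(stats) == 0L) stop("no loci", call. = FALSE)
  data.frame(n_loci = nrow(stats),
             mean_maf = mean(stats$maf, na.rm = TRUE),
             mean_pic = mean(stats$pic, na.rm = TRUE),
             mean_he = mean(stats$he, na.rm = TRUE),
             mean_ho = mean(stats$ho, na.rm = TRUE),
             mean_call_rate = mean(stats$call_rate, na.rm = TRUE))
}

#' Genome-wide nucleotide diversity per bp
#'
#' Per segregating site `pi = 2 p q n / (n - 1)` (`n` = called allele
#' count); the genome-wide value divides the sum over sites by the total
#' reference length. Monomorphic sites contribute 0.
#'
#' @param x a [genotype_matrix()].
#' @param genome_length_bp total reference length in bp; must cover the
#'   span of the loci.
#' @return list with `pi_bp` (per-bp nucleotide diversity), `pi_sum`
#'   (summed per-site diversity), and `n_segregating`.
#' @export
nucleotide_diversity <- function(x, genome_length_bp) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (genome_length_bp <= 0)
    stop("genome_length_bp must be > 0", call. = FALSE)
  span <- sum(tapply(x$loci$pos, x$loci$chrom, max))
  if (genome_length_bp < span)
    stop("genome_length_bp is smaller than the span of the loci",
         call. = FALSE)
  st <- locus_diversity(x, hwe = FALSE)
  pi_site <- st$pi_site
  pi_site[is.na(pi_site)] <- 0
  list(pi_bp = sum(pi_site) / genome_length_bp, pi_sum = sum(pi_site),
       n_segregating = sum(pi_site > 0))
}

# Weir & Cockerham (1984) variance components for one pair of
# populations, vectorised over loci. Returns per-locus a, b, c.
wc_components_pair <- function(G1, G2) {
  r <- 2
  n1 <- colSums(!is.na(G1))
  n2 <- colSums(!is.na(G2))
  p1 <- colMeans(G1, na.rm = TRUE) / 2
  p2 <- colMeans(G2, na.rm = TRUE) / 2
  h1 <- colSums(G1 == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(G2 == 1L, na.rm = TRUE) / pmax(n2, 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- n1 >= 2L & n2 >= 2L & is.finite(a) & is.finite(b) & is.finite(cc) &
    (a + b + cc) != 0
  list(a = a, b = b, c = cc, ok = ok)
}

#' Pairwise weighted Weir-Cockerham FST
#'
#' Per locus, the 1984 variance components `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals)
#' are computed from genotype counts, including the heterozygosity term.
#' The weighted estimator for a population pair is
#' `sum(a) / sum(a + b + c)` across usable loci; loci where either
#' population has fewer than 2 called samples, or where the components
#' are undefined, are skipped and counted.
#'
#' @param x a [genotype_matrix()].
#' @param labels named character/factor vector mapping samples to
#'   populations (names are sample ids), or an unnamed vector aligned
#'   with `sample_ids(x)`.
#' @return data.frame with one row per unordered population pair:
#'   `pop_a`, `pop_b`, `fst_weighted`, `n_loci_used`, `n_loci_skipped`.
#' @export
weir_cockerham_fst <- function(x, labels) {
  stopifnot(inherits(x, "genotype_matrix"))
  ids <- sample_ids(x)
  if (!is.null(names(labels))) labels <- labels[ids]
  if (length(labels) != length(ids) || any(is.na(labels)))
    stop("labels must cover every sample", call. = FALSE)
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("every population needs at least 2 samples", call. = FALSE)
  pairs <- combn(pops, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    A <- pairs[1L, k]
    B <- pairs[2L, k]
    comp <- wc_components_pair(x$dosage[labels == A, , drop = FALSE],
                               x$dosage[labels == B, , drop = FALSE])
    ok <- comp$ok
    out[[k]] <- data.frame(
      pop_a = A, pop_b = B,
      fst_weighted = sum(comp$a[ok]) /
        sum(comp$a[ok] + comp$b[ok] + comp$c[ok]),
      n_loci_used = sum(ok), n_loci_skipped = sum(!ok),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay profile
#'
#' Computes pairwise genotypic r-squared for intra-chromosomal locus
#' pairs within `max_dist_bp` (subsampled to `max_pairs` with a fixed
#' seed), bins by physical distance, and locates by linear interpolation
#' between bin midpoints the distance where the mean r-squared falls to
#' half its maximum and where it reaches 0.1. Intended for the full,
#' non-pruned site set.
#'
#' @param x a [genotype_matrix()].
#' @param max_dist_bp largest pair distance considered.
#' @param bin_width_bp distance bin width.
#' @param max_pairs pair budget; pairs beyond it are dropped by seeded
#'   subsampling.
#' @param seed subsampling seed.
#' @return list with `profile` (data.frame `bin_mid`, `n_pairs`,
#'   `mean_r2`; empty bins are reported with `n_pairs = 0` and excluded
#'   from interpolation), `half_decay_bp`, `r2_01_bp` (either is `NaN`
#'   when the curve never crosses the level).
#' @export
ld_decay <- function(x, max_dist_bp = 500e3, bin_width_bp = 10e3,
                     max_pairs = 2e6, seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  pos <- x$loci$pos
  chrom <- x$loci$chrom
  pair_i <- integer(0)
  pair_j <- integer(0)
  for (ci in split(seq_len(n_loci(x)), chrom)) {
    pc <- pos[ci]
    hi <- findInterval(pc + max_dist_bp, pc)
    cnt <- hi - seq_along(ci)
    has <- cnt > 0
    if (!any(has)) next
    ii <- rep(seq_along(ci)[has], cnt[has])
    jj <- unlist(lapply(seq_along(ci)[has],
                        function(a) (a + 1L):hi[a]), use.names = FALSE)
    pair_i <- c(pair_i, ci[ii])
    pair_j <- c(pair_j, ci[jj])
  }
  if (length(pair_i) == 0L)
    stop("no intra-chromosomal locus pairs within max_dist_bp",
         call. = FALSE)
  if (length(pair_i) > max_pairs) {
    sel <- with_seed(derive_seed(seed, "ld_decay"),
                     sample.int(length(pair_i), max_pairs))
    pair_i <- pair_i[sel]
    pair_j <- pair_j[sel]
  }
  d <- pos[pair_j] - pos[pair_i]

  G <- x$dosage
  r2 <- numeric(length(pair_i))
  chunk <- 50000L
  for (s in seq(1L, length(pair_i), by = chunk)) {
    e <- min(s + chunk - 1L, length(pair_i))
    A <- G[, pair_i[s:e], drop = FALSE]
    B <- G[, pair_j[s:e], drop = FALSE]
    M <- (!is.na(A)) & (!is.na(B))
    A[!M] <- 0L
    B[!M] <- 0L
    m <- colSums(M)
    sa <- colSums(A); sb <- colSums(B)
    saa <- colSums(A * A); sbb <- colSums(B * B)
    sab <- colSums(A * B)
    cov <- sab - sa * sb / m
    va <- saa - sa^2 / m
    vb <- sbb - sb^2 / m
    r2[s:e] <- ifelse(m >= 2 & va > 0 & vb > 0, cov^2 / (va * vb), NaN)
  }

  breaks <- seq(0, max_dist_bp, by = bin_width_bp)
  if (breaks[length(breaks)] < max_dist_bp)
    breaks <- c(breaks, max_dist_bp)
  bin <- cut(d, breaks, include.lowest = TRUE)
  mean_r2 <- tapply(r2, bin, mean, na.rm = TRUE)
  n_pairs <- tapply(!is.na(r2), bin, sum)
  n_pairs[is.na(n_pairs)] <- 0
  mids <- (head(breaks, -1) + breaks[-1]) / 2
  profile <- data.frame(bin_mid = mids, n_pairs = as.integer(n_pairs),
                        mean_r2 = as.numeric(mean_r2))
  cross_at <- function(level) {
    ok <- profile$n_pairs > 0 & is.finite(profile$mean_r2)
    xm <- profile$bin_mid[ok]
    ym <- profile$mean_r2[ok]
    if (length(ym) == 0L || ym[1L] < level) return(NaN)
    below <- which(ym < level)
    below <- below[below > 1L]
    if (length(below) == 0L) return(NaN)
    i <- below[1L]
    xm[i - 1L] + (ym[i - 1L] - level) / (ym[i - 1L] - ym[i]) *
      (xm[i] - xm[i - 1L])
  }
  mx <- suppressWarnings(max(profile$mean_r2[profile$n_pairs > 0],
                             na.rm = TRUE))
  list(profile = profile,
       half_decay_bp = if (is.finite(mx)) cross_at(mx / 2) else NaN,
       r2_01_bp = cross_at(0.1))
}
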