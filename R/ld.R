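#' Pairwise genotypic linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of alternate-allele dosages over mutually
#' called samples (composite LD on unphased genotypes).
#'
#' @param dosage_a,dosage_b equal-length dosage vectors (0/1/2/`NA`).
#' @return r-squared in `[0, 1]`; `NaN` when fewer than 2 mutually
#'   called entries remain or either vector has zero variance (such
#'   pairs are treated as not prunable).
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) return(NaN)
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (var(a) == 0 || var(b) == 0) return(NaN)
  cor(a, b)^2
}

# Greedy removal inside one window of locus indices (columns of G).
# Pairs exceeding r2_max are processed in decreasing r2 order; within a
# pair the locus with the lower MAF is removed (ties: the later
# (chrom, pos), i.e. the larger column index).
prune_window_greedy <- function(G, idx, maf, r2_max) {
  if (length(idx) < 2L) return(integer(0))
  r2 <- suppressWarnings(cor(G[, idx, drop = FALSE],
                             use = "pairwise.complete.obs"))^2
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 0
  removed <- logical(length(idx))
  repeat {
    r2[removed, ] <- 0
    r2[, removed] <- 0
    m <- max(r2)
    if (m <= r2_max) break
    hit <- which(r2 == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    a <- hit[1L, 1L]
    b <- hit[1L, 2L]
    drop <- if (maf[idx[a]] < maf[idx[b]]) a
            else if (maf[idx[b]] < maf[idx[a]]) b
            else max(a, b)
    removed[drop] <- TRUE
  }
  idx[removed]
}

#' Windowed LD pruning
#'
#' Slides a window of `window` currently retained SNPs along each
#' chromosome, advancing by `step` SNPs. Within a window, while any pair
#' exceeds `r2_max`, the pair with the highest r-squared is resolved by
#' removing its lower-MAF member (ties: the later locus). Windows never
#' span chromosomes and the output is deterministic.
#'
#' @param x a [genotype_matrix()] with loci sorted by (chrom, pos).
#' @param window window size in SNPs.
#' @param step step size in SNPs.
#' @param r2_max r-squared ceiling.
#' @return list with `keep` (logical over loci of `x`), `matrix` (the
#'   pruned [genotype_matrix()]), and `report` (an [attrition_report()]
#'   for sites).
#' @export
ld_prune <- function(x, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(inherits(x, "genotype_matrix"))
  G <- x$dosage
  p <- allele_freq(x)$p_alt
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- rep(TRUE, n_loci(x))
  for (ci in split(seq_len(n_loci(x)), x$loci$chrom)) {
    s <- 1L
    repeat {
      kept_here <- ci[keep[ci]]
      if (s > length(kept_here)) break
      win <- kept_here[s:min(s + window - 1L, length(kept_here))]
      if (length(win) >= 2L)
        keep[prune_window_greedy(G, win, maf, r2_max)] <- FALSE
      if (s + window - 1L >= length(kept_here)) break
      s <- s + step
    }
  }
  report <- attrition_report("sites", n_loci(x),
                             data.frame(label = sprintf(
                               "LD pruning (%d-SNP window, %d-SNP step, r2 > %g)",
                               window, step, r2_max), removed = sum(!keep)))
  list(keep = keep, matrix = x[, keep], report = report)
}
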