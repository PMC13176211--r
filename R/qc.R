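#' Quality-control thresholds
#'
#' Default values follow common PLINK-style practice for germplasm
#' resequencing panels: samples with more than 20\% missing genotypes
#' are dropped, then sites with more than 5\% missingness, exact
#' Hardy-Weinberg p below 1e-5, or minor allele frequency below 0.05;
#' LD pruning uses 50-SNP windows, a 5-SNP step, and r-squared 0.5.
#' All thresholds are strict (`>` for missingness, `<` for HWE p and
#' MAF).
#'
#' @param mind sample missingness ceiling.
#' @param geno site missingness ceiling.
#' @param hwe_p Hardy-Weinberg exact-test p-value floor.
#' @param maf_min minor-allele-frequency floor.
#' @param prune_window,prune_step,prune_r2 LD-pruning window size (SNPs),
#'   step (SNPs), and r-squared ceiling.
#' @param f_sd number of standard deviations defining an
#'   inbreeding-coefficient outlier.
#' @param ibs_dup,pihat_dup near-identity thresholds on IBS and PI_HAT.
#' @param min_overlap minimum number of mutually called loci for a
#'   confident pairwise comparison.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(mind = 0.2, geno = 0.05, hwe_p = 1e-5, maf_min = 0.05,
                      prune_window = 50, prune_step = 5, prune_r2 = 0.5,
                      f_sd = 3, ibs_dup = 0.98, pihat_dup = 0.98,
                      min_overlap = 100) {
  stopifnot(mind >= 0, mind <= 1, geno >= 0, geno <= 1,
            hwe_p >= 0, hwe_p <= 1, maf_min >= 0, maf_min <= 0.5,
            prune_window >= 2, prune_step >= 1, prune_r2 >= 0, prune_r2 <= 1,
            f_sd > 0, ibs_dup >= 0, ibs_dup <= 1,
            pihat_dup >= 0, pihat_dup <= 1, min_overlap >= 1)
  structure(list(mind = mind, geno = geno, hwe_p = hwe_p, maf_min = maf_min,
                 prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step), prune_r2 = prune_r2,
                 f_sd = f_sd, ibs_dup = ibs_dup, pihat_dup = pihat_dup,
                 min_overlap = as.integer(min_overlap)),
            class = "qc_config")
}

#' Per-sample call rate and inbreeding coefficient
#'
#' The expected homozygous count for sample `i` is the sum over its
#' called loci of `1 - 2 p (1 - p) * 2n / (2n - 1)`, using cohort-wide
#' allele frequencies `p` and called allele counts `2n` (the standard
#' small-sample correction). The method-of-moments inbreeding
#' coefficient is then `F = (obs_hom - exp_hom) / (n_called - exp_hom)`.
#' Loci with fewer than two called alleles are excluded.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @return data.frame with columns `sample`, `call_rate`, `n_called`,
#'   `obs_hom`, `exp_hom`, `f`.
#' @export
sample_call_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_samples(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  G <- x$dosage
  af <- allele_freq(x)
  usable <- af$n_alleles >= 2L
  p <- af$p_alt
  het_exp <- 2 * p * (1 - p) * af$n_alleles / pmax(af$n_alleles - 1L, 1L)
  het_exp[!usable] <- NA_real_

  called <- !is.na(G)
  n_called_all <- rowSums(called)
  calledu <- called[, usable, drop = FALSE]
  n_called <- rowSums(calledu)
  obs_hom <- rowSums(G[, usable, drop = FALSE] != 1L & calledu, na.rm = TRUE)
  exp_hom <- as.vector(calledu %*% (1 - het_exp[usable]))
  den <- n_called - exp_hom
  f <- ifelse(abs(den) > 1e-12, (obs_hom - exp_hom) / den, NA_real_)
  data.frame(sample = sample_ids(x),
             call_rate = n_called_all / n_loci(x),
             n_called = n_called, obs_hom = obs_hom, exp_hom = exp_hom,
             f = f, stringsAsFactors = FALSE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided conditional exact test: given the observed allele counts,
#' all compatible heterozygote counts are enumerated with probability
#' proportional to `n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa`, and the p-value
#' is the sum of probabilities not exceeding that of the observed
#' configuration (no mid-p adjustment). Monomorphic sites return 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors are accepted and
#'   tested elementwise).
#' @return vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == length(n_Aa), length(n_Aa) == length(n_aa))
  mapply(hwe_exact_one, n_AA, n_Aa, n_aa)
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(is.na(c(n_AA, n_Aa, n_aa))))
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("at least one called genotype required", call. = FALSE)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  ## feasible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  haa <- (rare - hets) / 2L            # rare-homozygote count
  hAA <- n - hets - haa
  logp <- lgamma(n + 1) - lgamma(hAA + 1) - lgamma(hets + 1) -
    lgamma(haa + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_Aa, hets)
  sum(pr[pr <= pr[obs] * (1 + 1e-9)])
}

# HWE exact p-values for every locus of a genotype matrix.
hwe_test_matrix <- function(x) {
  G <- x$dosage
  n_aa_ <- colSums(G == 2L, na.rm = TRUE)
  n_Aa_ <- colSums(G == 1L, na.rm = TRUE)
  n_AA_ <- colSums(G == 0L, na.rm = TRUE)
  any_call <- (n_AA_ + n_Aa_ + n_aa_) > 0L
  p <- rep(1, n_loci(x))
  p[any_call] <- hwe_exact_test(n_AA_[any_call], n_Aa_[any_call],
                                n_aa_[any_call])
  p
}

#' Remove samples exceeding the missingness ceiling
#'
#' @param x a [genotype_matrix()].
#' @param config a [qc_config()]; samples with missing fraction strictly
#'   above `config$mind` are removed.
#' @return list with `matrix`, `report` (an [attrition_report()] for
#'   samples), and `removed` (data.frame of removed samples and their
#'   missing fractions).
#' @export
filter_samples <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "genotype_matrix"))
  miss <- rowMeans(is.na(x$dosage))
  drop <- miss > config$mind
  report <- attrition_report("samples", n_samples(x),
                             data.frame(label = sprintf("missingness > %g",
                                                        config$mind),
                                        removed = sum(drop)))
  list(matrix = x[!drop, ], report = report,
       removed = data.frame(sample = sample_ids(x)[drop],
                            missing_rate = miss[drop],
                            stringsAsFactors = FALSE))
}

#' Site-level filtering with attrition bookkeeping
#'
#' Applies, in order: (1) site missingness strictly above
#' `config$geno`; (2) Hardy-Weinberg exact p strictly below
#' `config$hwe_p` (computed on the post-missingness matrix); (3) minor
#' allele frequency strictly below `config$maf_min`. The fixed order
#' matters and is part of the contract.
#'
#' @param x a [genotype_matrix()].
#' @param config a [qc_config()].
#' @return list with `matrix` and `report` (an [attrition_report()] for
#'   sites with one row per step).
#' @export
filter_sites <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_loci(x) == 0L) stop("matrix has no loci", call. = FALSE)
  report <- attrition_report("sites", n_loci(x))

  miss <- colMeans(is.na(x$dosage))
  keep <- miss <= config$geno
  report <- add_stage(report, sprintf("site missingness > %g", config$geno),
                      sum(!keep))
  x <- x[, keep]

  if (n_loci(x) > 0L) {
    hp <- hwe_test_matrix(x)
    keep <- hp >= config$hwe_p
  } else keep <- logical(0)
  report <- add_stage(report, sprintf("HWE exact p < %g", config$hwe_p),
                      sum(!keep))
  x <- x[, keep]

  if (n_loci(x) > 0L) {
    p <- allele_freq(x)$p_alt
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    keep <- maf >= config$maf_min
  } else keep <- logical(0)
  report <- add_stage(report, sprintf("MAF < %g", config$maf_min), sum(!keep))
  x <- x[, keep]

  if (n_loci(x) == 0L)
    warning("all sites removed by filtering", call. = FALSE)
  list(matrix = x, report = report)
}

#' Flag inbreeding-coefficient outliers
#'
#' Single-pass screen: mean and standard deviation of `F` are computed
#' once over all samples, and samples with `|F - mean| > f_sd * sd` are
#' flagged. A zero standard deviation flags nothing.
#'
#' @param stats data.frame from [sample_call_stats()].
#' @param f_sd outlier threshold in standard deviations.
#' @return character vector of flagged sample ids.
#' @export
detect_het_outliers <- function(stats, f_sd = 3) {
  if (nrow(stats) < 3L)
    stop("need at least 3 samples to screen F outliers", call. = FALSE)
  f <- stats$f
  m <- mean(f, na.rm = TRUE)
  s <- sd(f, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(character(0))
  stats$sample[!is.na(f) & abs(f - m) > f_sd * s]
}

#' Pairwise IBS / PI_HAT relatedness screen
#'
#' Identity-by-state for a pair is the mean fraction of shared alleles
#' over mutually called loci (per-locus sharing is `2 - |g_a - g_b|` out
#' of 2). PI_HAT is the PLINK-style method-of-moments relatedness
#' estimate: observed counts of IBS states 0/1/2 are equated with their
#' expectations under IBD states 0/1/2 given cohort allele frequencies;
#' the resulting IBD-state proportions are clamped to `[0, 1]` and
#' renormalised, and `PI_HAT = P(IBD=2) + P(IBD=1) / 2`. Pairs whose
#' overlap falls below `config$min_overlap` are marked low-confidence
#' and never flagged.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @param config a [qc_config()]; pairs with `ibs >= ibs_dup` or
#'   `pi_hat > pihat_dup` are flagged as near-duplicates.
#' @return data.frame with one row per unordered pair: `sample_a`,
#'   `sample_b`, `n_overlap`, `ibs`, `distance` (`1 - ibs`), `pi_hat`,
#'   `low_confidence`, `flagged`.
#' @export
relatedness_screen <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- n_samples(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  G <- x$dosage
  M0 <- (!is.na(G) & G == 0L) * 1
  M1 <- (!is.na(G) & G == 1L) * 1
  M2 <- (!is.na(G) & G == 2L) * 1
  Called <- M0 + M1 + M2

  N_ov <- tcrossprod(Called)
  ibs0 <- tcrossprod(M0, M2) + tcrossprod(M2, M0)
  ibs2 <- tcrossprod(M0) + tcrossprod(M1) + tcrossprod(M2)
  ibs1 <- N_ov - ibs0 - ibs2
  ibs <- (2 * N_ov - (2 * ibs0 + ibs1)) / (2 * N_ov)

  ## per-locus IBS-state probabilities under each IBD state, averaged
  ## over loci (missingness assumed independent of genotype)
  af <- allele_freq(x)
  ok <- af$n_alleles >= 2L & !is.nan(af$p_alt)
  p <- af$p_alt[ok]
  q <- 1 - p
  e0_ibd0 <- mean(2 * p^2 * q^2)
  e1_ibd0 <- mean(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- mean(2 * p * q)
  e2_ibd1 <- 1 - e1_ibd1

  P0 <- ibs0 / (N_ov * e0_ibd0)
  P1 <- (ibs1 - P0 * N_ov * e1_ibd0) / (N_ov * e1_ibd1)
  P2 <- (ibs2 - P0 * N_ov * e2_ibd0 - P1 * N_ov * e2_ibd1) / N_ov
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  pihat <- (P2 + P1 / 2) / ifelse(tot > 0, tot, 1)

  ut <- which(upper.tri(N_ov), arr.ind = TRUE)
  ids <- sample_ids(x)
  out <- data.frame(
    sample_a = ids[ut[, 1L]], sample_b = ids[ut[, 2L]],
    n_overlap = N_ov[ut], ibs = ibs[ut], distance = 1 - ibs[ut],
    pi_hat = pihat[ut],
    low_confidence = N_ov[ut] < config$min_overlap,
    stringsAsFactors = FALSE)
  out$flagged <- !out$low_confidence &
    (out$ibs >= config$ibs_dup | out$pi_hat > config$pihat_dup)
  out
}

#' Pairwise genetic distance matrix (1 - IBS)
#'
#' @param x a [genotype_matrix()].
#' @return symmetric `n x n` matrix of `1 - IBS` distances.
#' @export
ibs_distance <- function(x) {
  rel <- relatedness_screen(x, qc_config(min_overlap = 1))
  ids <- sample_ids(x)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  idx <- cbind(match(rel$sample_a, ids), match(rel$sample_b, ids))
  d[idx] <- rel$distance
  d[idx[, c(2, 1), drop = FALSE]] <- rel$distance
  d
}
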