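#' Fingerprinting-panel design constraints
#'
#' Defaults mirror a compact 150-SNP identification panel: biallelic
#' candidates with per-locus missingness at most 5\%, MAF above 0.25,
#' PIC above 0.25 and heterozygote informativeness `P(AB)` above 0.30,
#' mutual r-squared below 0.2 and at least 1 Mb spacing within a
#' chromosome, spread as evenly as candidate availability allows across
#' the chromosomes.
#'
#' @param size_target desired panel size.
#' @param maf_min MAF floor (strict `>`).
#' @param pic_min PIC floor (strict `>`).
#' @param het_min heterozygote-informativeness floor (strict `>`).
#' @param r2_max pairwise r-squared ceiling within the panel (strict
#'   `<`).
#' @param max_missing per-locus missingness ceiling (inclusive).
#' @param min_spacing_bp minimum spacing between panel loci on the same
#'   chromosome.
#' @param het_mode `"observed"` uses the observed heterozygote fraction
#'   for the `P(AB)` criterion; `"expected"` uses `2pq`.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(size_target = 150, maf_min = 0.25, pic_min = 0.25,
                         het_min = 0.30, r2_max = 0.2, max_missing = 0.05,
                         min_spacing_bp = 1e6,
                         het_mode = c("observed", "expected")) {
  het_mode <- match.arg(het_mode)
  stopifnot(size_target >= 1, maf_min >= 0, maf_min <= 0.5,
            pic_min >= 0, pic_min <= 0.375, het_min >= 0, het_min <= 1,
            r2_max >= 0, r2_max <= 1, max_missing >= 0, max_missing <= 1,
            min_spacing_bp >= 0)
  structure(list(size_target = as.integer(size_target), maf_min = maf_min,
                 pic_min = pic_min, het_min = het_min, r2_max = r2_max,
                 max_missing = max_missing, min_spacing_bp = min_spacing_bp,
                 het_mode = het_mode), class = "panel_config")
}

#' Select a fingerprinting panel
#'
#' Selection proceeds in four steps: (1) marginal candidate filter
#' (missingness, MAF, PIC, heterozygote informativeness); (2) per-
#' chromosome quotas by round-robin allocation of the size target over
#' the chromosomes present; (3) within each chromosome, greedy selection
#' in decreasing PIC order (ties: higher MAF, then earlier position),
#' accepting a candidate only if its r-squared with every already
#' selected locus on that chromosome stays below `r2_max` and its
#' spacing from them is at least `min_spacing_bp`; (4) unfilled quota is
#' redistributed to chromosomes with remaining acceptable candidates,
#' largest candidate surplus first. If the target still cannot be met
#' the spec is returned with a shortfall flag.
#'
#' @param x the curated [genotype_matrix()].
#' @param stats per-locus statistics from [locus_diversity()] computed
#'   on `x`.
#' @param config a [panel_config()].
#' @return object of class `panel_spec`: list with `loci` (selected
#'   locus metadata ordered by chrom, pos), `per_chrom` (table of
#'   counts), `constraints` (per-filter candidate pass counts),
#'   `shortfall`, `config`.
#' @export
select_panel <- function(x, stats, config = panel_config()) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "panel_config"))
  if (!identical(stats$id, x$loci$id))
    stop("stats must be computed on the same matrix", call. = FALSE)
  het <- if (config$het_mode == "observed") stats$ho else stats$he
  miss <- 1 - stats$call_rate
  pass_miss <- !is.na(miss) & miss <= config$max_missing
  pass_maf <- !is.na(stats$maf) & stats$maf > config$maf_min
  pass_pic <- !is.na(stats$pic) & stats$pic > config$pic_min
  pass_het <- !is.na(het) & het > config$het_min
  cand <- pass_miss & pass_maf & pass_pic & pass_het
  constraints <- data.frame(
    constraint = c(sprintf("missingness <= %g", config$max_missing),
                   sprintf("MAF > %g", config$maf_min),
                   sprintf("PIC > %g", config$pic_min),
                   sprintf("P(AB) > %g (%s)", config$het_min,
                           config$het_mode),
                   "all marginal filters"),
    n_pass = c(sum(pass_miss), sum(pass_maf), sum(pass_pic), sum(pass_het),
               sum(cand)))
  if (!any(cand)) stop("no candidate loci satisfy the marginal filters",
                       call. = FALSE)

  chroms <- unique(x$loci$chrom)
  n_chrom <- length(chroms)
  quota <- setNames(rep(config$size_target %/% n_chrom, n_chrom), chroms)
  extra <- config$size_target %% n_chrom
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L

  G <- x$dosage
  pos <- x$loci$pos
  ## candidate order within chromosome: PIC desc, MAF desc, pos asc
  cand_by_chrom <- lapply(chroms, function(ch) {
    idx <- which(cand & x$loci$chrom == ch)
    idx[order(-stats$pic[idx], -stats$maf[idx], pos[idx])]
  })
  names(cand_by_chrom) <- chroms

  acceptable <- function(j, sel) {
    if (length(sel) == 0L) return(TRUE)
    if (any(abs(pos[sel] - pos[j]) < config$min_spacing_bp)) return(FALSE)
    r2 <- vapply(sel, function(s) ld_r2(G[, j], G[, s]), 0)
    all(is.nan(r2) | r2 < config$r2_max)
  }

  selected <- setNames(vector("list", n_chrom), chroms)
  remaining <- cand_by_chrom
  take <- function(ch, want) {
    sel <- selected[[ch]]
    pool <- remaining[[ch]]
    got <- 0L
    used <- logical(length(pool))
    for (ii in seq_along(pool)) {
      if (got >= want) break
      if (acceptable(pool[ii], sel)) {
        sel <- c(sel, pool[ii])
        used[ii] <- TRUE
        got <- got + 1L
      }
    }
    selected[[ch]] <<- sel
    remaining[[ch]] <<- pool[!used]
    got
  }
  for (ch in chroms) take(ch, quota[[ch]])

  total <- length(unlist(selected))
  while (total < config$size_target) {
    surplus <- vapply(remaining, length, 0L)
    order_ch <- chroms[order(-surplus)]
    added <- 0L
    for (ch in order_ch) {
      if (total + added >= config$size_target) break
      if (length(remaining[[ch]]) == 0L) next
      added <- added + take(ch, 1L)
    }
    if (added == 0L) break
    total <- total + added
  }

  sel_idx <- sort(unlist(selected))
  loci <- cbind(x$loci[sel_idx, , drop = FALSE],
                stats[sel_idx, c("maf", "ho", "he", "pic", "call_rate"),
                      drop = FALSE])
  rownames(loci) <- NULL
  per_chrom <- table(factor(loci$chrom, levels = chroms))
  structure(list(loci = loci, per_chrom = per_chrom,
                 constraints = constraints,
                 shortfall = nrow(loci) < config$size_target,
                 config = config), class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("panel_spec: %d loci over %d chromosomes%s\n", nrow(x$loci),
              sum(x$per_chrom > 0),
              if (x$shortfall) " (SHORTFALL: below size target)" else ""))
  invisible(x)
}

#' Probability of identity for a set of biallelic loci
#'
#' Per locus with allele frequencies `p, q`:
#' `PI = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2` and the sibling variant
#' `PIsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' Cumulative values are products over loci, accumulated in log space.
#' A fixed locus (frequency 0 or 1) contributes 1 and triggers a
#' warning.
#'
#' @param freqs vector of alternate-allele frequencies in `[0, 1]`.
#' @return list with `pi`, `pi_sibs`, `log10_pi`, `log10_pi_sibs`, and
#'   `per_locus` (data.frame `p`, `pi_locus`, `pi_sibs_locus`).
#' @export
probability_of_identity <- function(freqs) {
  p <- as.numeric(freqs)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  fixed <- p == 0 | p == 1
  if (any(fixed))
    warning(sum(fixed), " fixed locus/loci contribute PI = 1", call. = FALSE)
  q <- 1 - p
  s2 <- p^2 + q^2
  s4 <- p^4 + q^4
  pi_l <- s4 + (2 * p * q)^2
  pisib_l <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  pi_l[fixed] <- 1
  pisib_l[fixed] <- 1
  l10 <- sum(log10(pi_l))
  l10s <- sum(log10(pisib_l))
  list(pi = 10^l10, pi_sibs = 10^l10s, log10_pi = l10, log10_pi_sibs = l10s,
       per_locus = data.frame(p = p, pi_locus = pi_l,
                              pi_sibs_locus = pisib_l))
}

#' Summary metrics of a fingerprinting panel
#'
#' @param x the [genotype_matrix()] the panel was selected from.
#' @param spec a [select_panel()] result.
#' @return list with mean/range of PIC, observed heterozygosity and
#'   per-locus missingness over the panel loci; cumulative `pi` and
#'   `pi_sibs` from the cohort allele frequencies at those loci; and the
#'   [uniqueness_check()] verdict.
#' @export
panel_metrics <- function(x, spec) {
  stopifnot(inherits(spec, "panel_spec"))
  sub <- x[, spec$loci$id]
  st <- locus_diversity(sub, hwe = FALSE)
  poi <- probability_of_identity(allele_freq(sub)$p_alt)
  uq <- uniqueness_check(x, spec)
  list(n_loci = nrow(spec$loci),
       pic_mean = mean(st$pic), pic_range = range(st$pic),
       ho_mean = mean(st$ho), ho_range = range(st$ho),
       missing_mean = mean(1 - st$call_rate),
       missing_range = range(1 - st$call_rate),
       pi = poi$pi, pi_sibs = poi$pi_sibs,
       log10_pi = poi$log10_pi, log10_pi_sibs = poi$log10_pi_sibs,
       uniqueness = uq)
}

#' Multilocus-profile uniqueness check
#'
#' Counts genotype mismatches for every sample pair at the mutually
#' called panel loci. Pairs with zero mismatches over at least
#' `min_overlap` loci are indistinguishable; the verdict is `TRUE` iff
#' no such pair exists. Pairs with insufficient overlap are reported
#' separately and not flagged.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @param spec a [select_panel()] result.
#' @param min_overlap minimum mutually called loci for a comparable
#'   pair.
#' @return list with `distinct` (verdict), `conflicts` (data.frame of
#'   indistinguishable pairs), `insufficient` (data.frame of pairs with
#'   too little overlap).
#' @export
uniqueness_check <- function(x, spec, min_overlap = 100) {
  stopifnot(inherits(spec, "panel_spec"))
  if (n_samples(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  sub <- x[, spec$loci$id]
  G <- sub$dosage
  M0 <- (!is.na(G) & G == 0L) * 1
  M1 <- (!is.na(G) & G == 1L) * 1
  M2 <- (!is.na(G) & G == 2L) * 1
  n_ov <- tcrossprod(M0 + M1 + M2)
  match_ct <- tcrossprod(M0) + tcrossprod(M1) + tcrossprod(M2)
  mismatch <- n_ov - match_ct
  ut <- which(upper.tri(n_ov), arr.ind = TRUE)
  ids <- sample_ids(x)
  ov <- n_ov[ut]
  mm <- mismatch[ut]
  conflicts <- data.frame(sample_a = ids[ut[, 1L]], sample_b = ids[ut[, 2L]],
                          n_overlap = ov, mismatches = mm,
                          stringsAsFactors = FALSE)
  insufficient <- conflicts[ov < min_overlap, , drop = FALSE]
  conflicts <- conflicts[ov >= min_overlap & mm == 0L, , drop = FALSE]
  list(distinct = nrow(conflicts) == 0L, conflicts = conflicts,
       insufficient = insufficient)
}
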