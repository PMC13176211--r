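#' Specify a synthetic admixed cohort
#'
#' Describes a diploid cohort drawn from `K` Balding-Nichols ancestral
#' populations with Dirichlet-distributed admixture, distance-dependent
#' linkage disequilibrium imposed by a quantile-copying chain, and
#' per-site/per-sample missingness. The defaults emulate a germplasm
#' resequencing panel: 64 samples, three ancestry groups whose pairwise
#' differentiation spans roughly FST 0.048-0.089, a flat folded allele
#' frequency spectrum, and LD whose mean r-squared halves on a ~39 kb
#' physical scale.
#'
#' @param n_samples number of diploid samples.
#' @param n_pops number of ancestral populations `K`.
#' @param divergence per-population Balding-Nichols drift parameter
#'   `F_k` in (0, 1); recycled to length `n_pops`. Between two
#'   populations the expected pairwise Weir-Cockerham FST is
#'   approximately `(F_a + F_b) / 2`; the defaults solve that system for
#'   the pairwise targets 0.048, 0.065 and 0.089.
#' @param alpha Dirichlet concentration per population for individual
#'   ancestry proportions; small values (default 0.1) yield many
#'   near-pure individuals plus strongly admixed ones.
#' @param pop_sizes optional integer vector of length `n_pops`; when
#'   given, samples are assigned deterministically to populations in
#'   blocks of these sizes with no admixture (used for
#'   differentiation-recovery experiments). Overrides `alpha`.
#' @param chrom_lengths chromosome lengths in bp (default 20 chromosomes
#'   of 20 Mb).
#' @param snp_spacing mean distance between adjacent loci in bp; loci
#'   are placed on a regular grid of this spacing.
#' @param ld_scale copy-chain scale lambda in bp. Along a chromosome the
#'   latent frequency-quantile state is copied from the previous locus
#'   with probability `exp(-d / lambda)`, giving haplotype correlation
#'   `exp(-D / lambda)` over distance `D` and therefore genotype
#'   r-squared decaying as `exp(-2D / lambda)`: the mean r-squared
#'   half-decay distance is `lambda * log(2) / 2`. The default 90,000 bp
#'   reproduces a measured half-decay near 39.4 kb.
#' @param ancestral_maf_law function of `n` returning `n` ancestral
#'   allele frequencies; truncated to `[0.05, 0.95]` downstream.
#' @param site_missing_rate mean per-site missing-call rate.
#' @param sample_missing_rate per-sample missing-call rate (scalar or
#'   length `n_samples`).
#' @param segment_mean_loci mean length, in loci, of the geometric
#'   ancestry segments carried by each gamete.
#' @param seed integer seed; a fixed seed makes the simulated VCF
#'   byte-identical across runs.
#' @return an object of class `cohort_model`.
#' @export
cohort_model <- function(n_samples = 64,
                         n_pops = 3,
                         divergence = c(0.072, 0.024, 0.106),
                         alpha = 0.1,
                         pop_sizes = NULL,
                         chrom_lengths = rep(20e6, 20),
                         snp_spacing = 10e3,
                         ld_scale = 90e3,
                         ancestral_maf_law = function(n) runif(n, 0.05, 0.95),
                         site_missing_rate = 0.01,
                         sample_missing_rate = 0.01,
                         segment_mean_loci = 100,
                         seed = 1L) {
  divergence <- rep_len(divergence, n_pops)
  alpha <- rep_len(alpha, n_pops)
  if (any(divergence <= 0) || any(divergence >= 1))
    stop("divergence (F_k) must lie in (0, 1)", call. = FALSE)
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chrom_lengths must be > 0", call. = FALSE)
  if (site_missing_rate < 0 || site_missing_rate > 1 ||
      any(sample_missing_rate < 0) || any(sample_missing_rate > 1))
    stop("missing rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(pop_sizes)) {
    pop_sizes <- as.integer(pop_sizes)
    if (length(pop_sizes) != n_pops || sum(pop_sizes) != n_samples)
      stop("pop_sizes must have length n_pops and sum to n_samples",
           call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_pops = as.integer(n_pops),
    divergence = divergence, alpha = alpha, pop_sizes = pop_sizes,
    chrom_lengths = chrom_lengths, snp_spacing = snp_spacing,
    ld_scale = ld_scale, ancestral_maf_law = ancestral_maf_law,
    site_missing_rate = site_missing_rate,
    sample_missing_rate = rep_len(sample_missing_rate, n_samples),
    segment_mean_loci = segment_mean_loci,
    seed = as.integer(seed)), class = "cohort_model")
}

# Regular locus grid implied by the model: one row per locus.
cohort_loci <- function(model) {
  chroms <- sprintf("chr%02d", seq_along(model$chrom_lengths))
  pos <- lapply(model$chrom_lengths, function(len)
    seq(model$snp_spacing, len, by = model$snp_spacing))
  chrom <- rep(chroms, vapply(pos, length, 1L))
  pos <- unlist(pos, use.names = FALSE)
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = paste0(chrom, "_", as.integer(pos)),
             stringsAsFactors = FALSE)
}

#' Draw Balding-Nichols population allele frequencies
#'
#' For each locus an ancestral frequency `p_j` is drawn from the model's
#' ancestral frequency law (truncated to `[0.05, 0.95]`) and each
#' population's frequency from a Beta distribution with mean `p_j` and
#' variance `F_k p_j (1 - p_j)` (Balding-Nichols parameterisation with
#' shape parameters `p_j (1 - F_k) / F_k` and
#' `(1 - p_j)(1 - F_k) / F_k`).
#'
#' @param model a [cohort_model()].
#' @param n_loci number of loci; defaults to the model's locus grid.
#' @return a `n_pops x n_loci` frequency matrix with attribute `p_anc`
#'   (the ancestral frequencies). Seeded by `model$seed`.
#' @export
draw_population_frequencies <- function(model, n_loci = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  if (is.null(n_loci)) n_loci <- nrow(cohort_loci(model))
  with_seed(derive_seed(model$seed, "freqs"),
            draw_population_frequencies_impl(model, n_loci))
}

draw_population_frequencies_impl <- function(model, n_loci) {
  p <- pmin(pmax(model$ancestral_maf_law(n_loci), 0.05), 0.95)
  K <- model$n_pops
  f <- matrix(NA_real_, K, n_loci)
  for (k in seq_len(K)) {
    Fk <- model$divergence[k]
    f[k, ] <- rbeta(n_loci, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  attr(f, "p_anc") <- p
  f
}

#' Simulate an admixed diploid cohort
#'
#' Each sample's ancestry proportions are Dirichlet draws (or fixed
#' population blocks when the model sets `pop_sizes`). Each of its two
#' gametes is a mosaic of ancestry segments with geometric lengths;
#' within a chromosome, the latent allele-frequency quantile of locus
#' `j` copies that of locus `j - 1` with probability
#' `exp(-d / ld_scale)` and is otherwise redrawn, so pairwise genotype
#' r-squared declines approximately as `exp(-2D / ld_scale)` with
#' physical distance `D`. Missing calls are then masked at the model's
#' per-site and per-sample rates.
#'
#' @param model a [cohort_model()].
#' @return a list with `matrix` (a [genotype_matrix()]) and `truth`, a
#'   list holding `Q_true` (`n x K` ancestry proportions, rows sum to
#'   1), `freqs_true` (`K x L` population frequencies), `p_anc`, and an
#'   empty `defect_labels` data.frame (filled by [inject_defects()]).
#' @export
simulate_cohort <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  loci <- cohort_loci(model)
  L <- nrow(loci)
  n <- model$n_samples
  K <- model$n_pops
  f <- draw_population_frequencies(model, L)
  p_anc <- attr(f, "p_anc")

  with_seed(derive_seed(model$seed, "cohort"), {
    ## ancestry proportions
    if (is.null(model$pop_sizes)) {
      Q <- matrix(rgamma(n * K, shape = rep(model$alpha, each = n)), n, K)
      Q <- Q / rowSums(Q)
    } else {
      Q <- matrix(0, n, K)
      Q[cbind(seq_len(n), rep(seq_len(K), model$pop_sizes))] <- 1
    }

    n_gam <- 2L * n
    ## per-gamete ancestry segments (geometric lengths in loci)
    Z <- matrix(0L, n_gam, L)
    pgeo <- 1 / model$segment_mean_loci
    chrom_idx <- split(seq_len(L), loci$chrom)
    for (g in seq_len(n_gam)) {
      i <- (g + 1L) %/% 2L
      for (ci in chrom_idx) {
        lc <- length(ci)
        filled <- 0L
        while (filled < lc) {
          seg <- rgeom(1L, pgeo) + 1L
          seg <- min(seg, lc - filled)
          k <- sample.int(K, 1L, prob = Q[i, ])
          Z[g, ci[(filled + 1L):(filled + seg)]] <- k
          filled <- filled + seg
        }
      }
    }

    ## copying chain over quantile states, vectorised across gametes
    H <- matrix(0L, n_gam, L)
    for (ci in chrom_idx) {
      u <- runif(n_gam)
      d <- diff(loci$pos[ci])
      for (jj in seq_along(ci)) {
        j <- ci[jj]
        if (jj > 1L) {
          fresh <- runif(n_gam) >= exp(-d[jj - 1L] / model$ld_scale)
          if (any(fresh)) u[fresh] <- runif(sum(fresh))
        }
        H[, j] <- as.integer(u < f[cbind(Z[, j], j)])
      }
    }
    G <- H[seq(1L, n_gam, by = 2L), , drop = FALSE] +
      H[seq(2L, n_gam, by = 2L), , drop = FALSE]

    ## missingness: per-site rates vary around the mean, plus per-sample rates
    site_rate <- if (model$site_missing_rate > 0)
      runif(L, 0, 2 * model$site_missing_rate) else rep(0, L)
    miss_p <- pmin(outer(model$sample_missing_rate, site_rate, `+`), 1)
    mask <- matrix(runif(n * L) < miss_p, n, L)
    G[mask] <- NA_integer_
  })

  ref_alt <- with_seed(derive_seed(model$seed, "alleles"), {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(ref = ref, alt = alt)
  })
  loci$ref <- ref_alt$ref
  loci$alt <- ref_alt$alt

  samples <- sprintf("S%03d", seq_len(n))
  rownames(G) <- samples
  gm <- genotype_matrix(G, loci, samples = samples)
  rownames(Q) <- samples
  truth <- list(Q_true = Q, freqs_true = f, p_anc = p_anc,
                defect_labels = data.frame(sample = character(),
                                           defect = character(),
                                           param = numeric(),
                                           stringsAsFactors = FALSE))
  list(matrix = gm, truth = truth)
}

#' Describe QC defects to plant in a cohort
#'
#' @param high_missing target overall missing fractions for
#'   high-missingness samples (defaults mirror two real removals with
#'   missing fractions 0.5031 and 0.2843).
#' @param f_outliers target inbreeding coefficients for heterozygosity
#'   outliers (one inbred-like, one excess-heterozygous).
#' @param duplicate logical; plant a near-duplicate sample?
#' @param duplicate_flip fraction of the duplicate's called genotypes to
#'   flip to a different value.
#' @return a list of class `defect_spec`.
#' @export
defect_spec <- function(high_missing = c(0.5031, 0.2843),
                        f_outliers = c(0.5, -0.5),
                        duplicate = TRUE,
                        duplicate_flip = 0.005) {
  if (any(high_missing < 0) || any(high_missing > 1) ||
      duplicate_flip < 0 || duplicate_flip > 1)
    stop("defect fractions must lie in [0, 1]", call. = FALSE)
  structure(list(high_missing = high_missing, f_outliers = f_outliers,
                 duplicate = isTRUE(duplicate),
                 duplicate_flip = duplicate_flip), class = "defect_spec")
}

#' Plant QC defects into a simulated cohort
#'
#' Selects distinct target samples (seeded) and (a) masks random calls
#' of the high-missingness targets until each reaches its target overall
#' missing fraction, (b) perturbs one sample toward excess homozygosity
#' and one toward excess heterozygosity to approximate the requested
#' inbreeding coefficients, and (c) appends a near-duplicate copy of a
#' clean sample with a small fraction of its called genotypes flipped.
#'
#' @param x a [genotype_matrix()].
#' @param spec a [defect_spec()].
#' @param seed integer seed controlling defect placement.
#' @return list with `matrix` (the modified [genotype_matrix()]) and
#'   `labels`, a data.frame of planted defects (`sample`, `defect`,
#'   `param`).
#' @export
inject_defects <- function(x, spec = defect_spec(), seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(spec, "defect_spec"))
  G <- x$dosage
  n <- nrow(G)
  L <- ncol(G)
  p <- allele_freq(x)$p_alt
  labels <- list()

  with_seed(derive_seed(seed, "defects"), {
    n_targets <- length(spec$high_missing) + length(spec$f_outliers) +
      as.integer(spec$duplicate)
    if (n_targets > n)
      stop("more defects requested than samples available", call. = FALSE)
    targets <- sample.int(n, n_targets)
    ti <- 0L

    for (rate in spec$high_missing) {
      ti <- ti + 1L
      i <- targets[ti]
      cur <- mean(is.na(G[i, ]))
      need <- max(0, round((rate - cur) * L))
      called <- which(!is.na(G[i, ]))
      if (need > 0 && length(called) > 0)
        G[i, sample(called, min(need, length(called)))] <- NA_integer_
      labels[[length(labels) + 1L]] <-
        data.frame(sample = rownames(G)[i], defect = "high_missing",
                   param = rate, stringsAsFactors = FALSE)
    }

    for (f_target in spec$f_outliers) {
      ti <- ti + 1L
      i <- targets[ti]
      gi <- G[i, ]
      if (f_target >= 0) {
        ## convert a fraction f_target of het calls to homozygotes,
        ## splitting 0/2 evenly so allele frequency stays unbiased
        het <- which(!is.na(gi) & gi == 1L)
        conv <- het[runif(length(het)) < f_target]
        gi[conv] <- ifelse(runif(length(conv)) < 0.5, 0L, 2L)
      } else {
        ## convert homozygotes to hets at locus-specific rates so that
        ## observed het ~= (1 - f_target) * expected het
        hom <- which(!is.na(gi) & gi != 1L)
        he <- 2 * p[hom] * (1 - p[hom])
        pr <- pmin(1, -f_target * he / pmax(1 - he, 1e-9))
        conv <- hom[runif(length(hom)) < pr]
        gi[conv] <- 1L
      }
      G[i, ] <- gi
      labels[[length(labels) + 1L]] <-
        data.frame(sample = rownames(G)[i], defect = "f_outlier",
                   param = f_target, stringsAsFactors = FALSE)
    }

    if (spec$duplicate) {
      ti <- ti + 1L
      src <- targets[ti]
      dup <- G[src, , drop = TRUE]
      called <- which(!is.na(dup))
      n_flip <- round(spec$duplicate_flip * length(called))
      if (n_flip > 0) {
        fl <- sample(called, n_flip)
        dup[fl] <- vapply(dup[fl], function(g)
          sample(setdiff(0:2, g), 1L), 0L)
      }
      dup_id <- paste0("DUP_", rownames(G)[src])
      G <- rbind(G, dup)
      rownames(G)[nrow(G)] <- dup_id
      labels[[length(labels) + 1L]] <-
        data.frame(sample = dup_id, defect = "duplicate",
                   param = spec$duplicate_flip, stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <-
        data.frame(sample = rownames(G)[src], defect = "duplicate_source",
                   param = spec$duplicate_flip, stringsAsFactors = FALSE)
    }
  })

  list(matrix = genotype_matrix(G, x$loci, samples = rownames(G)),
       labels = do.call(rbind, labels))
}

#' Write simulation ground truth as TSV files
#'
#' @param truth the `truth` element returned by [simulate_cohort()],
#'   optionally with `defect_labels` filled in.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- data.frame(sample = rownames(truth$Q_true), truth$Q_true,
                  check.names = FALSE)
  names(q)[-1L] <- paste0("Q", seq_len(ncol(truth$Q_true)))
  write_tsv(q, file.path(dir, "q_true.tsv"))
  f <- data.frame(pop = seq_len(nrow(truth$freqs_true)), truth$freqs_true,
                  check.names = FALSE)
  write_tsv(f, file.path(dir, "freqs_true.tsv"))
  if (!is.null(truth$defect_labels) && nrow(truth$defect_labels) > 0)
    write_tsv(truth$defect_labels, file.path(dir, "defect_labels.tsv"))
  invisible(dir)
}
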