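#' Allele-frequency-scaled principal component analysis
#'
#' Each locus is centred by `2 p` and scaled by `sqrt(2 p (1 - p))`
#' (drift-variance scaling); missing entries are mean-imputed (zero
#' after centring) and monomorphic loci are dropped. Scores and
#' explained-variance fractions come from the singular value
#' decomposition of the resulting matrix.
#'
#' @param x a [genotype_matrix()] with at least 2 samples; an LD-pruned
#'   input is recommended.
#' @param n_components number of components to return (must be smaller
#'   than the number of samples).
#' @return list with `scores` (`n x n_components`, rownames = sample
#'   ids), `explained` (fraction of variance per returned component),
#'   `degenerate` (`TRUE` when the matrix carries no variance at all).
#' @export
genotype_pca <- function(x, n_components = 10) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- n_samples(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (n_components >= n)
    stop("n_components must be smaller than the number of samples",
         call. = FALSE)
  G <- x$dosage
  af <- allele_freq(x)
  p <- af$p_alt
  keep <- !is.nan(p) & p > 0 & p < 1
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(G, 2L, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), `/`)
  if (ncol(X) == 0L || all(abs(X) < 1e-12)) {
    scores <- matrix(0, n, n_components,
                     dimnames = list(sample_ids(x),
                                     paste0("PC", seq_len(n_components))))
    return(list(scores = scores, explained = rep(0, n_components),
                degenerate = TRUE))
  }
  X <- sweep(X, 2L, colMeans(X))  # recentre after imputation
  sv <- svd(X, nu = n, nv = 0)
  ev <- sv$d^2
  expl <- ev / sum(ev)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- sample_ids(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       degenerate = FALSE)
}

#' Maximum-likelihood admixture via EM
#'
#' Fits the binomial admixture model `g_ij ~ Binomial(2, theta_ij)` with
#' `theta_ij = sum_k q_ik f_kj` over missing-masked entries by EM
#' (closed-form updates of ancestry proportions `Q` and cluster allele
#' frequencies `F`), keeping the best of several seeded restarts. The
#' log-likelihood is non-decreasing across iterations; cluster
#' frequencies are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param x a [genotype_matrix()]; an LD-pruned input is assumed (the
#'   model treats loci as unlinked).
#' @param K number of ancestry clusters (`1 <= K <= n_samples`).
#' @param seed integer seed for the restarts.
#' @param tol convergence threshold on the log-likelihood gain.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of seeded restarts.
#' @param f_min floor applied to the cluster allele frequencies (they
#'   are kept in `[f_min, 1 - f_min]`); raise it (e.g. to `1/(2n)`) when
#'   the fit is used to predict held-out genotypes.
#' @return object of class `admixture_fit`: list with `K`, `Q` (`n x K`,
#'   rows sum to 1), `F` (`K x L`), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `seed`.
#' @export
admixture_em <- function(x, K, seed = 1L, tol = 1e-6, max_iter = 2000,
                         n_restarts = 5, f_min = 1e-6) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- n_samples(x)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K must not exceed the number of samples", call. = FALSE)
  G <- x$dosage
  G[is.na(G)] <- -1L
  storage.mode(G) <- "integer"
  p_hat <- allele_freq(x)$p_alt
  p_hat[is.nan(p_hat)] <- 0.5

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, paste0("admix", r)), {
      Q0 <- matrix(rgamma(n * K, 1), n, K)
      Q0 <- Q0 / rowSums(Q0)
      F0 <- matrix(pmin(pmax(rep(p_hat, each = K) +
                               runif(K * length(p_hat), -0.1, 0.1),
                             1e-3), 1 - 1e-3), K, length(p_hat))
      list(Q0 = Q0, F0 = F0)
    })
    fit <- admixture_em_cpp(G, init$Q0, init$F0, tol, as.integer(max_iter),
                            f_min, TRUE)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- sample_ids(x)
  colnames(best$F) <- x$loci$id
  structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                 loglik = best$loglik, loglik_trace = best$trace,
                 iterations = best$iterations, converged = best$converged,
                 seed = as.integer(seed)), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "admixture_fit: K = %d, n = %d, loglik = %.2f, %d iterations%s\n",
    x$K, nrow(x$Q), x$loglik, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Hold-out cross-validation over the number of clusters
#'
#' For each fold a random share of the called genotype entries is
#' masked, the model is fitted on the remainder, and the masked entries
#' are scored by their mean binomial deviance against the fitted
#' `2 * theta`. The cross-validation error for a given `K` averages the
#' folds; the best `K` is the arg-min. Fold fits floor the cluster
#' allele frequencies at `1/(2 n)` (one-allele smoothing): without it
#' the unbounded deviance of held-out genotypes at near-fixed fitted
#' frequencies dominates the error and biases the selection toward
#' small `K`.
#'
#' @param x a [genotype_matrix()].
#' @param K_range candidate cluster counts.
#' @param folds number of folds (>= 2).
#' @param seed integer seed (drives fold assignment and the EM
#'   restarts).
#' @param tol,max_iter,n_restarts EM settings per fold (fewer restarts
#'   than [admixture_em()]'s default keep cross-validation affordable).
#' @return list with `cv` (data.frame `K`, `cv_error`) and `best_K`.
#' @export
admixture_cv <- function(x, K_range = 2:10, folds = 5, seed = 1L,
                         tol = 1e-4, max_iter = 2000, n_restarts = 1) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (folds < 2L) stop("cross-validation needs at least 2 folds",
                       call. = FALSE)
  G0 <- x$dosage
  called <- which(!is.na(G0))
  fold_of <- with_seed(derive_seed(seed, "cvfolds"),
                       sample(rep_len(seq_len(folds), length(called))))
  err <- matrix(NA_real_, length(K_range), folds)
  for (fi in seq_len(folds)) {
    held <- called[fold_of == fi]
    Gm <- G0
    Gm[held] <- NA_integer_
    ## loci left with no calls in this fold cannot inform the fit
    has_call <- colSums(!is.na(Gm)) > 0L
    xm <- genotype_matrix(Gm, x$loci, samples = sample_ids(x))[, has_call]
    col_of <- ((held - 1L) %/% nrow(G0)) + 1L
    usable <- has_call[col_of]
    held_u <- held[usable]
    for (ki in seq_along(K_range)) {
      fit <- admixture_em(xm, K_range[ki],
                          seed = derive_seed(seed, paste0("cv", fi)),
                          tol = tol, max_iter = max_iter,
                          n_restarts = n_restarts,
                          f_min = 1 / (2 * n_samples(x)))
      theta <- fit$Q %*% fit$F
      th_full <- matrix(NA_real_, nrow(G0), ncol(G0))
      th_full[, has_call] <- theta
      g <- G0[held_u]
      th <- pmin(pmax(th_full[held_u], 1e-9), 1 - 1e-9)
      dev <- 2 * (ifelse(g > 0, g * log(g / (2 * th)), 0) +
                    ifelse(g < 2, (2 - g) * log((2 - g) / (2 - 2 * th)), 0))
      err[ki, fi] <- mean(dev)
    }
  }
  cv <- data.frame(K = K_range, cv_error = rowMeans(err))
  list(cv = cv, best_K = K_range[which.min(cv$cv_error)], fold_errors = err)
}

#' Assign samples to clusters from an admixture fit
#'
#' Samples whose maximum ancestry proportion reaches `q_assign` are
#' labelled with that cluster (inclusive threshold); the rest are
#' `"admixed"`. Samples at or above `q_pure` are additionally flagged
#' near-pure.
#'
#' @param fit an [admixture_em()] fit.
#' @param q_assign assignment threshold on max Q.
#' @param q_pure near-pure threshold on max Q.
#' @return data.frame with `sample`, `cluster` (character cluster index
#'   or `"admixed"`), `max_q`, `near_pure`.
#' @export
assign_clusters <- function(fit, q_assign = 0.70, q_pure = 0.99) {
  stopifnot(inherits(fit, "admixture_fit"))
  max_q <- apply(fit$Q, 1L, max)
  which_k <- apply(fit$Q, 1L, which.max)
  data.frame(sample = rownames(fit$Q),
             cluster = ifelse(max_q >= q_assign, as.character(which_k),
                              "admixed"),
             max_q = max_q, near_pure = max_q >= q_pure,
             stringsAsFactors = FALSE)
}

#' k-means clustering with silhouette validation in PCA space
#'
#' Runs seeded multi-start k-means on the PCA scores for each candidate
#' `k` and scores each solution by the mean silhouette width on
#' Euclidean distances; the best `k` maximises the mean silhouette.
#'
#' @param pca result of [genotype_pca()] (or any list with a `scores`
#'   matrix).
#' @param k_range candidate cluster counts (all `< n_samples`).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return list with `silhouette` (data.frame `k`, `mean_silhouette`),
#'   `best_k`, and `labels` (cluster labels at `best_k`).
#' @export
kmeans_silhouette <- function(pca, k_range = 2:6, seed = 1L, nstart = 20) {
  scores <- pca$scores
  n <- nrow(scores)
  k_range <- as.integer(k_range)
  if (ncol(scores) < 2L) stop("need at least 2 components", call. = FALSE)
  if (any(k_range >= n))
    stop("k must be smaller than the number of samples", call. = FALSE)
  if (any(k_range < 2L)) stop("k must be at least 2", call. = FALSE)
  d <- dist(scores)
  res <- with_seed(derive_seed(seed, "kmeans"), {
    lapply(k_range, function(k) {
      km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
      sil <- cluster::silhouette(km$cluster, d)
      list(k = k, mean_sil = mean(sil[, "sil_width"]),
           labels = km$cluster)
    })
  })
  tab <- data.frame(k = vapply(res, `[[`, 1L, "k"),
                    mean_silhouette = vapply(res, `[[`, 1, "mean_sil"))
  best <- which.max(tab$mean_silhouette)
  list(silhouette = tab, best_k = tab$k[best], labels = res[[best]]$labels)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge
#' distance, so every leaf is equidistant from the root (ultrametric).
#' Ties are resolved deterministically by lexicographic label order.
#'
#' @param distances symmetric matrix (or `dist`) of non-negative
#'   distances with zero diagonal, e.g. from [ibs_distance()].
#' @return an \pkg{ape} `phylo` tree with branch lengths.
#' @export
upgma <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square",
                               call. = FALSE)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (any(!is.finite(d))) {
    idx <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite distance between %s and %s",
                 rownames(d)[idx[1L]], colnames(d)[idx[2L]]), call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("distances must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  ord <- order(rownames(d))       # lexicographic tie-break
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)               # heights halved: ultrametric UPGMA tree
}
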