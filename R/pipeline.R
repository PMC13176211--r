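#' Configure a full pipeline run
#'
#' Exactly one of `vcf` (a path to a multi-sample VCF) or `model` (a
#' [cohort_model()] to simulate) must be supplied.
#'
#' @param vcf optional input VCF path.
#' @param model optional [cohort_model()]; when given the cohort is
#'   simulated and, if `defects` is non-`NULL`, QC defects are planted.
#' @param defects optional [defect_spec()] applied to a simulated
#'   cohort.
#' @param qc a [qc_config()].
#' @param panel a [panel_config()].
#' @param k_range candidate cluster counts for admixture
#'   cross-validation; a single value skips cross-validation and fits
#'   that K directly.
#' @param cv_folds cross-validation folds.
#' @param genome_length_bp total reference length for nucleotide
#'   diversity; defaults to the simulated genome length or, for VCF
#'   input, the summed per-chromosome maximum position.
#' @param out_dir output directory for artifacts.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param ld_decay_run logical; also compute the LD-decay profile on the
#'   pre-pruning site set.
#' @return a list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, model = NULL, defects = NULL,
                       qc = qc_config(), panel = panel_config(),
                       k_range = 2:6, cv_folds = 5,
                       genome_length_bp = NULL, out_dir = "germprint_run",
                       seed = 1L, ld_decay_run = FALSE) {
  if (is.null(vcf) == is.null(model))
    stop("supply exactly one of vcf or model", call. = FALSE)
  stopifnot(inherits(qc, "qc_config"), inherits(panel, "panel_config"))
  if (!is.null(model)) stopifnot(inherits(model, "cohort_model"))
  if (!is.null(defects)) stopifnot(inherits(defects, "defect_spec"))
  structure(list(vcf = vcf, model = model, defects = defects, qc = qc,
                 panel = panel, k_range = k_range, cv_folds = cv_folds,
                 genome_length_bp = genome_length_bp, out_dir = out_dir,
                 seed = as.integer(seed), ld_decay_run = isTRUE(ld_decay_run)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

log_line <- function(quiet, stage, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes simulate (or read) -> sample QC -> site QC -> LD pruning ->
#' inbreeding-outlier and relatedness screens -> diversity statistics ->
#' population structure (PCA, admixture with cross-validation, k-means/
#' silhouette, UPGMA tree) -> fingerprinting panel, writing every table
#' as TSV, trees as Newick, genotypes as VCF, and a machine-readable
#' run summary as JSON. The summary contains no timestamps, so two runs
#' with the same configuration and seed produce byte-identical
#' summaries.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the run summary, invisibly (a nested list mirroring
#'   `summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out,
                             call. = FALSE)
  summary <- list(tool = "germprint",
                  version = as.character(packageVersion("germprint")),
                  seed = config$seed,
                  thresholds = c(unclass(config$qc),
                                 unclass(config$panel)[
                                   setdiff(names(unclass(config$panel)),
                                           "het_mode")]))

  ## ---- input ----
  truth <- NULL
  if (!is.null(config$model)) {
    sim <- stage("simulate", simulate_cohort(config$model))
    x <- sim$matrix
    truth <- sim$truth
    if (!is.null(config$defects)) {
      inj <- stage("inject_defects",
                   inject_defects(x, config$defects,
                                  seed = derive_seed(config$seed, "defects")))
      x <- inj$matrix
      truth$defect_labels <- inj$labels
    }
    stage("simulate", {
      write_vcf(x, file.path(out, "cohort.vcf"))
      write_truth(truth, file.path(out, "truth"))
    })
    genome_len <- config$genome_length_bp
    if (is.null(genome_len)) genome_len <- sum(config$model$chrom_lengths)
  } else {
    x <- stage("read_vcf", read_vcf(config$vcf))
    genome_len <- config$genome_length_bp
    if (is.null(genome_len))
      genome_len <- sum(tapply(x$loci$pos, x$loci$chrom, max))
  }
  log_line(quiet, "input", "%d samples x %d loci", n_samples(x), n_loci(x))
  summary$input <- list(n_samples = n_samples(x), n_loci = n_loci(x))

  ## ---- sample missingness ----
  fs <- stage("filter_samples", filter_samples(x, config$qc))
  x <- fs$matrix
  write_tsv(fs$removed, file.path(out, "samples_removed_missingness.tsv"))
  sample_attrition <- fs$report
  log_line(quiet, "qc", "removed %d high-missingness samples",
           sum(fs$report$removed))

  ## ---- site filters ----
  fi <- stage("filter_sites", filter_sites(x, config$qc))
  x <- fi$matrix
  site_attrition <- fi$report
  log_line(quiet, "qc", "site filters retained %d loci", n_loci(x))

  ## ---- LD decay (pre-pruning) ----
  ld_profile <- NULL
  if (config$ld_decay_run) {
    ld_profile <- stage("ld_decay",
                        ld_decay(x, seed = derive_seed(config$seed, "ld")))
    write_tsv(ld_profile$profile, file.path(out, "ld_decay_profile.tsv"))
    summary$ld_decay <- list(half_decay_bp = ld_profile$half_decay_bp,
                             r2_01_bp = ld_profile$r2_01_bp)
  }

  ## ---- LD pruning ----
  pr <- stage("ld_prune", ld_prune(x, config$qc$prune_window,
                                   config$qc$prune_step, config$qc$prune_r2))
  x <- pr$matrix
  site_attrition <- add_stage(site_attrition, pr$report$label[1L],
                              pr$report$removed[1L])
  log_line(quiet, "qc", "LD pruning retained %d loci", n_loci(x))

  ## ---- inbreeding outliers ----
  stats_before <- stage("sample_stats", sample_call_stats(x))
  write_tsv(stats_before, file.path(out, "sample_stats.tsv"))
  outliers <- stage("f_outliers", detect_het_outliers(stats_before,
                                                      config$qc$f_sd))
  sample_attrition <- add_stage(sample_attrition,
                                sprintf("inbreeding |F| > %g sd",
                                        config$qc$f_sd), length(outliers))
  x <- x[!(sample_ids(x) %in% outliers), ]
  log_line(quiet, "qc", "removed %d F outliers (%s)", length(outliers),
           paste(outliers, collapse = ", "))

  ## ---- relatedness ----
  rel <- stage("relatedness", relatedness_screen(x, config$qc))
  write_tsv(rel, file.path(out, "relatedness.tsv"))
  dup_pairs <- rel[rel$flagged, c("sample_a", "sample_b", "ibs", "pi_hat")]
  log_line(quiet, "qc", "%d near-duplicate pair(s) flagged", nrow(dup_pairs))

  write_tsv(sample_attrition, file.path(out, "attrition_samples.tsv"))
  write_tsv(site_attrition, file.path(out, "attrition_sites.tsv"))
  write_vcf(x, file.path(out, "curated.vcf"))

  ## ---- diversity ----
  st <- stage("diversity", locus_diversity(x))
  write_tsv(st, file.path(out, "locus_stats.tsv"))
  summ <- cohort_summary(st)
  nd <- stage("diversity", nucleotide_diversity(x, genome_len))
  summary$diversity <- list(n_loci = n_loci(x),
                            mean_maf = summ$mean_maf,
                            mean_pic = summ$mean_pic,
                            mean_he = summ$mean_he, mean_ho = summ$mean_ho,
                            pi_bp = nd$pi_bp)
  log_line(quiet, "diversity", "mean He %.4f, pi %.3g per bp",
           summ$mean_he, nd$pi_bp)

  ## ---- structure ----
  pca <- stage("pca", genotype_pca(x, n_components = min(10L,
                                                         n_samples(x) - 1L)))
  write_tsv(data.frame(sample = rownames(pca$scores), pca$scores),
            file.path(out, "pca_scores.tsv"))
  seed_adm <- derive_seed(config$seed, "admixture")
  if (length(config$k_range) > 1L) {
    cv <- stage("admixture_cv",
                admixture_cv(x, K_range = config$k_range,
                             folds = config$cv_folds, seed = seed_adm))
    write_tsv(cv$cv, file.path(out, "admixture_cv.tsv"))
    best_k <- cv$best_K
    summary$structure <- list(cv = cv$cv, best_K = best_k)
  } else {
    best_k <- config$k_range
    summary$structure <- list(best_K = best_k)
  }
  fit <- stage("admixture", admixture_em(x, best_k, seed = seed_adm))
  qdf <- data.frame(sample = rownames(fit$Q), fit$Q, check.names = FALSE)
  names(qdf)[-1L] <- paste0("Q", seq_len(fit$K))
  write_tsv(qdf, file.path(out, "admixture_q.tsv"))
  assign <- assign_clusters(fit)
  write_tsv(assign, file.path(out, "cluster_assignments.tsv"))
  summary$structure$loglik <- fit$loglik
  summary$structure$converged <- fit$converged
  summary$structure$cluster_counts <-
    as.list(table(assign$cluster))
  summary$structure$n_near_pure <- sum(assign$near_pure)

  km <- stage("kmeans", kmeans_silhouette(
    pca, k_range = config$k_range[config$k_range < n_samples(x)],
    seed = derive_seed(config$seed, "kmeans")))
  write_tsv(km$silhouette, file.path(out, "silhouette.tsv"))
  summary$structure$kmeans_best_k <- km$best_k
  summary$pca_explained <- pca$explained

  tree <- stage("upgma", upgma(ibs_distance(x)))
  write_newick(tree, file.path(out, "upgma.nwk"))

  ## cluster-wise diversity and FST need >= 2 assigned clusters
  lab <- assign$cluster[assign$cluster != "admixed"]
  if (length(unique(lab)) >= 2L) {
    keep <- assign$cluster != "admixed" &
      assign$cluster %in% names(which(table(lab) >= 2L))
    sub <- x[keep, ]
    fst <- stage("fst", weir_cockerham_fst(
      sub, setNames(assign$cluster[keep], assign$sample[keep])))
    write_tsv(fst, file.path(out, "fst_pairwise.tsv"))
    summary$fst <- fst
  }

  ## ---- panel ----
  spec <- stage("panel", select_panel(x, st, config$panel))
  write_tsv(spec$loci, file.path(out, "panel_loci.tsv"))
  pm <- stage("panel", panel_metrics(x, spec))
  summary$panel <- list(n_loci = pm$n_loci, pic_mean = pm$pic_mean,
                        ho_mean = pm$ho_mean,
                        log10_pi = pm$log10_pi,
                        log10_pi_sibs = pm$log10_pi_sibs,
                        all_profiles_distinct = pm$uniqueness$distinct,
                        shortfall = spec$shortfall)
  fps <- lapply(sample_ids(x), function(s) encode_fingerprint(x, spec, s))
  write_tsv(data.frame(sample = vapply(fps, `[[`, "", "sample"),
                       genotype = vapply(fps, `[[`, "", "genotype"),
                       payload = vapply(fps, `[[`, "", "payload"),
                       stringsAsFactors = FALSE),
            file.path(out, "fingerprints.tsv"))
  log_line(quiet, "panel", "%d loci, log10 PI %.2f, distinct = %s",
           pm$n_loci, pm$log10_pi, pm$uniqueness$distinct)

  summary$attrition <- list(
    samples = lapply(seq_len(nrow(sample_attrition)), function(i)
      as.list(sample_attrition[i, ])),
    sites = lapply(seq_len(nrow(site_attrition)), function(i)
      as.list(site_attrition[i, ])))
  summary$duplicates_flagged <- if (nrow(dup_pairs) > 0)
    lapply(seq_len(nrow(dup_pairs)), function(i) as.list(dup_pairs[i, ]))
  else list()
  summary$removed_samples <- list(
    missingness = fs$removed$sample,
    f_outliers = outliers)

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
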