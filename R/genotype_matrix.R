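#' Diploid biallelic genotype matrix
#'
#' The container consumed by every stage of the pipeline: an
#' `n_samples x n_loci` matrix of alternate-allele dosages (0, 1, 2, or
#' `NA` for a missing call) together with per-locus metadata.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param loci data.frame with one row per locus and columns `chrom`,
#'   `pos` (1-based bp), `id`, `ref`, `alt`. Single-base `ref`/`alt` in
#'   A/C/G/T, `ref != alt`, `(chrom, pos)` unique, rows sorted by
#'   `(chrom, pos)`.
#' @param samples character vector of sample identifiers; defaults to
#'   `rownames(dosage)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (named integer matrix) and `loci`.
#' @export
genotype_matrix <- function(dosage, loci, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required", call. = FALSE)
  samples <- as.character(samples)
  if (length(samples) != nrow(dosage))
    stop("length(samples) must equal nrow(dosage)", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers", call. = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(loci)))
    stop("loci must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (nrow(loci) != ncol(dosage))
    stop("nrow(loci) must equal ncol(dosage)", call. = FALSE)
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$id <- as.character(loci$id)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  validate_loci(loci)
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosage) <- samples
  colnames(dosage) <- loci$id
  rownames(loci) <- NULL
  structure(list(dosage = dosage, loci = loci), class = "genotype_matrix")
}

validate_loci <- function(loci) {
  if (nrow(loci) == 0L) return(invisible(loci))
  if (any(is.na(loci$pos)) || any(loci$pos < 1L))
    stop("locus positions must be 1-based integers >= 1", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  if (!all(loci$ref %in% bases) || !all(loci$alt %in% bases))
    stop("ref/alt alleles must be single bases in A/C/G/T", call. = FALSE)
  if (any(loci$ref == loci$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate locus coordinate: ", d, call. = FALSE)
  }
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci))))
    stop("loci must be sorted by (chrom, pos)", call. = FALSE)
  invisible(loci)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d samples x %d loci (%d chromosomes, %.2f%% missing)\n",
    n_samples(x), n_loci(x), length(unique(x$loci$chrom)), 100 * miss))
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(x) ncol(x$dosage)

#' Sample identifiers of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (integer, logical, or sample ids).
#' @param j locus index (integer, logical, or locus ids).
#' @param ... ignored.
#' @return a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(j)) j <- match(j, x$loci$id)
  d <- x$dosage[i, j, drop = FALSE]
  genotype_matrix(d, x$loci[seq_len(n_loci(x))[
    if (is.logical(j)) which(j) else j], , drop = FALSE],
    samples = rownames(d))
}

#' Per-locus alternate-allele frequency and called allele counts
#'
#' @param x a `genotype_matrix`.
#' @return data.frame with `id`, `n_alleles` (called allele count 2n),
#'   `p_alt` (alt-allele frequency among called alleles; `NaN` when no
#'   calls).
#' @export
allele_freq <- function(x) {
  called <- colSums(!is.na(x$dosage)) * 2L
  alt <- colSums(x$dosage, na.rm = TRUE)
  data.frame(id = x$loci$id, n_alleles = called,
             p_alt = ifelse(called > 0, alt / called, NaN),
             stringsAsFactors = FALSE)
}

#' Ordered attrition ledger for samples or sites
#'
#' Records how many entities each filtering stage removed and how many
#' remain, with the telescoping invariant
#' `retained[k] = retained[k-1] - removed[k]` enforced.
#'
#' @param entity `"samples"` or `"sites"`.
#' @param initial initial entity count before any filtering.
#' @param stages data.frame with columns `label` and `removed`
#'   (may have zero rows).
#' @return An object of class `attrition_report`: a data.frame with
#'   columns `label`, `removed`, `retained`, plus attributes `entity`
#'   and `initial`.
#' @export
attrition_report <- function(entity = c("samples", "sites"), initial,
                             stages = data.frame(label = character(),
                                                 removed = numeric())) {
  entity <- match.arg(entity)
  stopifnot(is.numeric(initial), length(initial) == 1L, initial >= 0)
  stages <- as.data.frame(stages, stringsAsFactors = FALSE)
  removed <- as.numeric(stages$removed)
  if (any(removed < 0)) stop("removed counts must be >= 0", call. = FALSE)
  retained <- initial - cumsum(removed)
  if (any(retained < 0))
    stop("attrition ledger removes more entities than remain", call. = FALSE)
  out <- data.frame(label = as.character(stages$label), removed = removed,
                    retained = retained, stringsAsFactors = FALSE)
  structure(out, entity = entity, initial = initial,
            class = c("attrition_report", "data.frame"))
}

#' Append a stage to an attrition report
#' @param report an `attrition_report`.
#' @param label stage label.
#' @param removed number of entities removed at this stage.
#' @return the extended `attrition_report`.
#' @export
add_stage <- function(report, label, removed) {
  stopifnot(inherits(report, "attrition_report"))
  stages <- data.frame(label = c(report$label, label),
                       removed = c(report$removed, removed),
                       stringsAsFactors = FALSE)
  attrition_report(attr(report, "entity"), attr(report, "initial"), stages)
}

#' Final retained count of an attrition report
#' @param report an `attrition_report`.
#' @return numeric retained count after the last stage (the initial
#'   count if no stage was recorded).
#' @export
attrition_retained <- function(report) {
  stopifnot(inherits(report, "attrition_report"))
  if (nrow(report) == 0L) attr(report, "initial")
  else report$retained[nrow(report)]
}

#' @export
print.attrition_report <- function(x, ...) {
  cat(sprintf("attrition_report (%s), initial = %s\n", attr(x, "entity"),
              format(attr(x, "initial"), big.mark = ",")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
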