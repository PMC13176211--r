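#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) and retains only biallelic
#' single-nucleotide records. Indels, multi-allelic and symbolic-allele
#' records are dropped and counted in the attached drop log. Phased and
#' unphased GT values are both accepted; half calls and `./.` become
#' missing.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param region_filter optional character vector of chromosome names to
#'   keep.
#' @return a [genotype_matrix()] with attribute `drop_log`, a named
#'   integer vector counting dropped records by reason
#'   (`indel`, `multiallelic`, `symbolic`, `region`).
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has an empty sample list", call. = FALSE)
  fmt <- gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF format error: GT field absent from FORMAT", call. = FALSE)
  samples <- colnames(gt)[-1L]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  symbolic <- grepl("[<>\\[\\]]", alt) | alt == "*"
  multi <- !symbolic & grepl(",", alt)
  indel <- !symbolic & !multi &
    (nchar(ref) != 1L | nchar(alt) != 1L | !(ref %in% bases) | !(alt %in% bases))
  keep <- !symbolic & !multi & !indel
  drop_log <- c(indel = sum(indel), multiallelic = sum(multi),
                symbolic = sum(symbolic), region = 0L)
  if (!is.null(region_filter)) {
    off <- keep & !(fix[, "CHROM"] %in% region_filter)
    drop_log["region"] <- sum(off)
    keep <- keep & !off
  }
  if (!any(keep))
    stop("no biallelic SNP records retained from ", path, call. = FALSE)

  fixk <- fix[keep, , drop = FALSE]
  key <- paste(fixk[, "CHROM"], fixk[, "POS"])
  if (anyDuplicated(key))
    stop("VCF format error: duplicate site ", key[duplicated(key)][1L],
         call. = FALSE)

  # GT is always the leading FORMAT key in VCF 4.x
  gtk <- sub(":.*$", "", gt[keep, -1L, drop = FALSE])
  dos <- matrix(NA_integer_, nrow = sum(keep), ncol = length(samples))
  dos[gtk %in% c("0/0", "0|0")] <- 0L
  dos[gtk %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gtk %in% c("1/1", "1|1")] <- 2L

  id <- fixk[, "ID"]
  id[is.na(id) | id == "."] <-
    paste0(fixk[, "CHROM"], "_", fixk[, "POS"])[is.na(id) | id == "."]
  loci <- data.frame(chrom = fixk[, "CHROM"],
                     pos = as.integer(fixk[, "POS"]),
                     id = id, ref = fixk[, "REF"], alt = fixk[, "ALT"],
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  out <- genotype_matrix(t(dos[ord, , drop = FALSE]),
                         loci[ord, , drop = FALSE], samples = samples)
  attr(out, "drop_log") <- drop_log
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a GT-only plain-text VCF; missing calls are written `./.` and
#' loci appear in (chrom, pos) order. The header records the writing
#' tool and version.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=germprint %s", as.character(packageVersion("germprint"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(x)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  g <- x$dosage
  calls <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  calls[ok] <- gt_code[g[ok] + 1L]
  lines <- paste(x$loci$chrom, x$loci$pos, x$loci$id, x$loci$ref, x$loci$alt,
                 ".", "PASS", ".", "GT",
                 apply(calls, 2L, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an \pkg{ape} `phylo` object with branch lengths, e.g. as
#'   returned by [upgma()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo"))
    stop("tree must be a 'phylo' object", call. = FALSE)
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 leaves", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in tree", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a headered, tab-delimited table
#'
#' Convenience wrapper used for all tabular reports.
#'
#' @param df a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
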