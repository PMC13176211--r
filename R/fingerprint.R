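# IUPAC two-base ambiguity codes, keyed by the sorted base pair.
iupac_het <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# CRC-32 (IEEE 802.3, polynomial 0xEDB88320), table-driven, on the
# UTF-8 bytes of a string. Returned as an 8-hex-digit string.
crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320 as signed int
      else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  crc <- -1L                                    # 0xFFFFFFFF
  for (b in bytes) {
    idx <- bitwAnd(bitwXor(crc, as.integer(b)), 255L)
    crc <- bitwXor(crc32_table[idx + 1L], bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  sprintf("%04x%04x", bitwAnd(bitwShiftR(crc, 16L), 65535L),
          bitwAnd(crc, 65535L))
}

# Order-sensitive hash of the panel's locus ids, used to tie a payload
# to the panel it was encoded against.
panel_hash <- function(spec) crc32_hex(paste(spec$loci$id, collapse = ","))

#' Encode a sample's panel genotype as a checksummed barcode payload
#'
#' The genotype string holds one IUPAC character per panel locus:
#' homozygotes are the base itself, heterozygotes the two-base ambiguity
#' code for ref/alt, missing calls `N`. The payload is
#' `"GP1|<panel-hash>|<sample-id>|<genotype-string>|<CRC32>"`, where the
#' checksum covers the first four fields. Rasterising the payload as a
#' QR image is left to any external encoder; the testable contract is
#' the payload itself.
#'
#' @param x a [genotype_matrix()].
#' @param spec a [select_panel()] result.
#' @param sample sample identifier present in `x`.
#' @return object of class `fingerprint`: list with `sample`,
#'   `genotype`, `payload`, `panel_hash`.
#' @export
encode_fingerprint <- function(x, spec, sample) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(spec, "panel_spec"))
  i <- match(sample, sample_ids(x))
  if (is.na(i)) stop("sample not found: ", sample, call. = FALSE)
  sub <- x[, spec$loci$id]
  g <- sub$dosage[i, ]
  ref <- spec$loci$ref
  alt <- spec$loci$alt
  het_key <- paste0(pmin(ref, alt), pmax(ref, alt))
  chars <- ifelse(is.na(g), "N",
                  ifelse(g == 0L, ref,
                         ifelse(g == 2L, alt, iupac_het[het_key])))
  geno <- paste(chars, collapse = "")
  ph <- panel_hash(spec)
  body <- paste("GP1", ph, sample, geno, sep = "|")
  structure(list(sample = sample, genotype = geno, panel_hash = ph,
                 payload = paste(body, crc32_hex(body), sep = "|")),
            class = "fingerprint")
}

#' Decode and verify a barcode payload
#'
#' @param payload a payload string produced by [encode_fingerprint()].
#' @return list with `sample`, `genotype`, `panel_hash`.
#' @export
decode_fingerprint <- function(payload) {
  parts <- strsplit(payload, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 5L || parts[1L] != "GP1")
    stop("not a GP1 fingerprint payload", call. = FALSE)
  body <- paste(parts[1:4], collapse = "|")
  if (!identical(crc32_hex(body), parts[5L]))
    stop("fingerprint payload failed its checksum", call. = FALSE)
  list(sample = parts[3L], genotype = parts[4L], panel_hash = parts[2L])
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint: %s (%d loci, panel %s)\n", x$sample,
              nchar(x$genotype), x$panel_hash))
  invisible(x)
}
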