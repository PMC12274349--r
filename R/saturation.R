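#' In-silico mutational saturation of a 5'UTR region
#'
#' Generates every possible single-nucleotide variant in the region: each
#' position is substituted with the three alternative bases. Output is
#' deterministic, ordered by position (5' to 3') then alternate base
#' (A < C < G < T).
#'
#' @param t A [transcript_model].
#' @param region Inclusive coding-position interval (vector or
#'   `"c.-303..c.-1"` string); defaults to the whole 5'UTR. Must lie
#'   within the 5'UTR.
#' @return data.frame with columns `c_pos`, `ref`, `alt`, `hgvs_c`;
#'   exactly `3 * region length` rows.
#' @examples
#' t <- transcript_model(utr5 = "ACGATGC", cds = "ATGAAATGA")
#' nrow(enumerate_snvs(t))   # 21
#' @export
enumerate_snvs <- function(t, region = NULL) {
  stopifnot(inherits(t, "transcript_model"))
  region <- resolve_utr_region(t, region)
  pos <- region[1]:region[2]
  idx <- c_to_index(t, pos)
  ref <- substring(t$seq, idx + 1L, idx + 1L)
  bases <- c("A", "C", "G", "T")
  c_pos <- rep(pos, each = 3L)
  ref3 <- rep(ref, each = 3L)
  alt <- unlist(lapply(ref, function(b) setdiff(bases, b)), use.names = FALSE)
  data.frame(c_pos = c_pos, ref = ref3, alt = alt,
             hgvs_c = paste0("c.", c_pos, ref3, ">", alt))
}

# validate an snv data.frame against the transcript; returns it normalised
validate_snvs <- function(t, snvs) {
  need <- c("c_pos", "ref", "alt")
  if (!all(need %in% names(snvs)))
    stop("snv table needs columns c_pos, ref, alt", call. = FALSE)
  if (nrow(snvs) == 0L) {
    snvs$hgvs_c <- character(0)
    return(snvs)
  }
  idx <- c_to_index(t, snvs$c_pos)
  actual <- substring(t$seq, idx + 1L, idx + 1L)
  bad <- which(actual != snvs$ref)
  if (length(bad) > 0L)
    stop(sprintf("REF mismatch at c.%d: transcript has %s, variant claims %s",
                 snvs$c_pos[bad[1]], actual[bad[1]], snvs$ref[bad[1]]),
         call. = FALSE)
  if (any(snvs$ref == snvs$alt))
    stop("alt must differ from ref", call. = FALSE)
  if (!all(c(snvs$ref, snvs$alt) %in% c("A", "C", "G", "T")))
    stop("ref and alt must be single A/C/G/T bases", call. = FALSE)
  snvs$hgvs_c <- paste0("c.", snvs$c_pos, snvs$ref, ">", snvs$alt)
  snvs
}

#' Transcript-space VCF output and input
#'
#' Variants are written as VCF 4.2 in transcript space: CONTIG is the
#' transcript id, POS the 1-based offset into the concatenated
#' 5'UTR + CDS sequence, and the INFO key `HGVSC` carries the HGVS c.
#' notation. `read_vcf()` is the exact inverse and validates every REF
#' base against the transcript.
#'
#' @param snvs data.frame of variants (`c_pos`, `ref`, `alt`).
#' @param t The [transcript_model] the variants refer to.
#' @param path Output/input file path.
#' @param info Optional character vector (one element per variant) of
#'   extra INFO content appended after the HGVSC key.
#' @param extra_headers Optional extra `##` header lines.
#' @return `write_vcf()` returns `path` invisibly; `read_vcf()` returns
#'   the variant data.frame.
#' @export
write_vcf <- function(snvs, t, path, info = NULL, extra_headers = NULL) {
  snvs <- validate_snvs(t, snvs)
  pos1 <- c_to_index(t, snvs$c_pos) + 1L
  info_col <- paste0("HGVSC=", snvs$hgvs_c)
  if (!is.null(info)) {
    stopifnot(length(info) == nrow(snvs))
    info_col <- ifelse(nzchar(info), paste0(info_col, ";", info), info_col)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", t$id, nchar(t$seq)),
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS c. notation in transcript space\">",
    extra_headers,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- paste(t$id, pos1, ".", snvs$ref, snvs$alt, ".", ".", info_col,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path, t) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  if (any(chrom != t$id))
    warning(sprintf("VCF contig '%s' differs from transcript id '%s'",
                    chrom[chrom != t$id][1], t$id))
  pos1 <- as.integer(fix[, "POS"])
  n <- nchar(t$seq)
  if (any(pos1 < 1L | pos1 > n))
    stop("VCF POS outside transcript", call. = FALSE)
  snvs <- data.frame(c_pos = index_to_c(t, pos1 - 1L),
                     ref = fix[, "REF"], alt = fix[, "ALT"])
  validate_snvs(t, snvs)
}
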