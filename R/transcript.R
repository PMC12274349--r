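#' Transcript model for 5'UTR upORF analysis
#'
#' A minimal single-isoform transcript representation: 5'UTR, CDS and an
#' optional 3'UTR, all in transcript orientation. The CDS must be a valid
#' open reading frame: length a positive multiple of 3, starting with ATG,
#' ending with a stop codon (TAA/TAG/TGA) and free of internal in-frame
#' stops. Sequences are upper-cased on construction and RNA alphabet (U) is
#' converted to DNA (T); ambiguity codes are rejected because every
#' downstream annotation is defined on a concrete base.
#'
#' @param utr5,cds,utr3 Nucleotide strings (A/C/G/T, case-insensitive,
#'   U accepted). `utr3` may be empty.
#' @param id Transcript identifier used as the VCF contig name.
#' @return An object of class `transcript_model`: a list with elements
#'   `id`, `utr5`, `cds`, `utr3`, `utr5_len` and `seq` (the concatenation).
#' @examples
#' t <- transcript_model(utr5 = "ACGATGC", cds = "ATGAAATGA")
#' t
#' @export
transcript_model <- function(utr5, cds, utr3 = "", id = "transcript") {
  utr5 <- clean_seq(utr5, "utr5")
  cds  <- clean_seq(cds, "cds")
  utr3 <- if (nzchar(utr3)) clean_seq(utr3, "utr3") else ""
  if (nchar(utr5) < 1L)
    stop("utr5 must contain at least one base", call. = FALSE)
  validate_cds(cds)
  structure(
    list(id = as.character(id), utr5 = utr5, cds = cds, utr3 = utr3,
         utr5_len = nchar(utr5), seq = paste0(utr5, cds, utr3)),
    class = "transcript_model"
  )
}

clean_seq <- function(x, what) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single string", what), call. = FALSE)
  x <- chartr("u", "t", tolower(x))
  x <- toupper(x)
  bad <- regmatches(x, regexpr("[^ACGT]", x))
  if (length(bad) > 0L)
    stop(sprintf("%s contains a non-ACGT character ('%s' at position %d); ambiguity codes are not supported",
                 what, bad, regexpr("[^ACGT]", x)), call. = FALSE)
  x
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_cds <- function(cds) {
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L)
    stop(sprintf("cds length (%d) must be a positive multiple of 3 with at least two codons", n),
         call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG")
    stop("cds must begin with ATG", call. = FALSE)
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  last <- codons[length(codons)]
  if (!last %in% STOP_CODONS)
    stop(sprintf("cds must end with a stop codon (TAA/TAG/TGA), found '%s'", last),
         call. = FALSE)
  internal <- which(codons[-length(codons)] %in% STOP_CODONS)
  if (length(internal) > 0L)
    stop(sprintf("cds has an internal in-frame stop codon '%s' at codon %d (nt %d)",
                 codons[internal[1]], internal[1], (internal[1] - 1L) * 3L + 1L),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model '%s'\n", x$id))
  cat(sprintf("  5'UTR: %d nt (c.-%d..c.-1)\n", x$utr5_len, x$utr5_len))
  cat(sprintf("  CDS:   %d nt (c.1..c.%d, %d codons incl. stop)\n",
              nchar(x$cds), nchar(x$cds), nchar(x$cds) / 3L))
  if (nzchar(x$utr3)) cat(sprintf("  3'UTR: %d nt\n", nchar(x$utr3)))
  invisible(x)
}

#' Load a transcript model from FASTA + sidecar config or GenBank
#'
#' Two input layouts are supported. (1) A FASTA file holding the transcript
#' (cDNA) sequence plus a YAML or JSON sidecar config giving either
#' `utr5_len` (CDS assumed to run to the last in-frame stop given
#' `cds_len`, or to the end of the record) or an explicit
#' `cds_start`/`cds_end` 1-based span. (2) A GenBank flat file with a CDS
#' feature (`start..end`), from which the UTRs are inferred.
#'
#' @param file Path to the FASTA or GenBank file.
#' @param config Path to the sidecar YAML/JSON config (FASTA input only),
#'   or a named list with the same fields.
#' @param which For multi-record FASTA, the record name or index to load.
#' @param id Optional identifier override; defaults to the record name.
#' @return A validated [transcript_model]. Invariant violations are
#'   reported with the offending rule and position.
#' @export
load_transcript <- function(file, config = NULL, which = 1L, id = NULL) {
  if (is_genbank(file)) {
    rec <- read_genbank_cds(file)
    seq <- rec$seq
    span <- c(rec$cds_start, rec$cds_end)
    if (is.null(id)) id <- rec$id
  } else {
    ss <- Biostrings::readDNAStringSet(file)
    if (length(ss) == 0L) stop("FASTA file contains no records", call. = FALSE)
    seq <- as.character(ss[[which]])
    nm <- names(ss)[if (is.numeric(which)) which else match(which, names(ss))]
    if (is.null(id)) id <- sub("\\s.*$", "", nm)
    if (is.null(config))
      stop("FASTA input needs a sidecar config with utr5_len or cds_start/cds_end",
           call. = FALSE)
    if (is.character(config)) config <- read_sidecar(config)
    span <- config_to_span(config, nchar(seq))
  }
  n <- nchar(seq)
  if (span[1] < 1L || span[2] > n || span[1] >= span[2])
    stop("CDS span outside the sequence record", call. = FALSE)
  if (span[1] == 1L)
    stop("transcript has an empty 5'UTR; at least one UTR base is required",
         call. = FALSE)
  transcript_model(
    utr5 = substr(seq, 1L, span[1] - 1L),
    cds  = substr(seq, span[1], span[2]),
    utr3 = if (span[2] < n) substr(seq, span[2] + 1L, n) else "",
    id = id
  )
}

read_sidecar <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else
    yaml::read_yaml(path)
}

config_to_span <- function(config, n) {
  if (!is.null(config$cds_start) && !is.null(config$cds_end)) {
    c(as.integer(config$cds_start), as.integer(config$cds_end))
  } else if (!is.null(config$utr5_len)) {
    start <- as.integer(config$utr5_len) + 1L
    end <- if (!is.null(config$cds_len)) start + as.integer(config$cds_len) - 1L else n
    c(start, end)
  } else {
    stop("config must provide utr5_len or cds_start/cds_end", call. = FALSE)
  }
}

is_genbank <- function(file) {
  head <- readLines(file, n = 1L, warn = FALSE)
  length(head) == 1L && grepl("^LOCUS", head)
}

# Minimal GenBank flat-file reader: LOCUS id, the first (single-interval)
# CDS feature, and the ORIGIN sequence block. Joined/complement locations
# are rejected - the model is a single-exon transcript-space record.
read_genbank_cds <- function(file) {
  lines <- readLines(file, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "genbank"
  cds_line <- grep("^\\s{5}CDS\\s", lines, value = TRUE)
  if (length(cds_line) == 0L)
    stop("GenBank record has no CDS feature", call. = FALSE)
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", cds_line[1]))
  m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
  if (length(m) == 0L)
    stop(sprintf("unsupported CDS location '%s' (single interval only)", loc),
         call. = FALSE)
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank record has no ORIGIN block", call. = FALSE)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end - 1L)]
  seq <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  list(id = id, seq = seq,
       cds_start = as.integer(m[2]), cds_end = as.integer(m[3]))
}

# Base accessor: zero-based index window [from, from+len-1]
tx_base <- function(t, idx) substr(t$seq, idx + 1L, idx + 1L)
tx_window <- function(seq, idx, len = 3L) substr(seq, idx + 1L, idx + len)
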