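#' Translation initiation codon sets
#'
#' The canonical start is ATG; the near-cognate set comprises the nine
#' codons differing from ATG at exactly one position (CTG, GTG, TTG, ACG,
#' AAG, AGG, ATA, ATC, ATT). `tis_codons()` returns the codon set selected
#' by a `tis_mode`.
#'
#' @param tis_mode One of `"canonical"` (ATG only), `"near_cognate"`
#'   (the nine single-mismatch codons) or `"both"`.
#' @return Character vector of codons.
#' @export
tis_codons <- function(tis_mode = c("both", "canonical", "near_cognate")) {
  tis_mode <- match.arg(tis_mode)
  switch(tis_mode,
         canonical = "ATG",
         near_cognate = NEAR_COGNATE,
         both = c("ATG", NEAR_COGNATE))
}

NEAR_COGNATE <- c("CTG", "GTG", "TTG", "ACG", "AAG", "AGG", "ATA", "ATC", "ATT")

#' Scan a 5'UTR region for upstream translation initiation sites
#'
#' Every triplet window whose first base lies in `region` (and whose three
#' bases are all inside the transcript) is tested against the codon set of
#' `tis_mode`. Windows may span the 5'UTR/CDS junction (e.g. a TIS at
#' c.-1 reads bases c.-1, c.1, c.2).
#'
#' @param t A [transcript_model].
#' @param region Inclusive coding-position interval for the first TIS
#'   base, as `c(start, end)` or a string `"c.-303..c.-1"`. Defaults to
#'   the whole 5'UTR. Must lie within the 5'UTR.
#' @param tis_mode See [tis_codons()].
#' @return data.frame with one row per site: `c_start`, `codon`,
#'   `canonical`, ordered 5' to 3'.
#' @examples
#' t <- transcript_model(utr5 = "ACGATGC", cds = "ATGAAATGA")
#' scan_tis(t, tis_mode = "canonical")   # the uATG at c.-4
#' scan_tis(t, tis_mode = "both")        # also the uACG at c.-7
#' @export
scan_tis <- function(t, region = NULL, tis_mode = "both") {
  stopifnot(inherits(t, "transcript_model"))
  region <- resolve_utr_region(t, region)
  codons <- tis_codons(tis_mode)
  scan_codons_df(t$seq, c_to_index(t, region[1]), c_to_index(t, region[2]),
                 codons, t)
}

resolve_utr_region <- function(t, region) {
  if (is.null(region)) return(c(-t$utr5_len, -1L))
  if (is.character(region)) region <- parse_c_region(region)
  region <- as.integer(region)
  if (region[1] < -t$utr5_len || region[2] > -1L)
    stop(sprintf("region must lie within the 5'UTR (c.-%d..c.-1)", t$utr5_len),
         call. = FALSE)
  region
}

# all windows with first index in [from, to] matching `codons`
scan_codons_df <- function(seq, from, to, codons, t) {
  to <- min(to, nchar(seq) - 3L)
  if (from > to)
    return(data.frame(c_start = integer(), codon = character(),
                      canonical = logical()))
  starts <- from:to
  win <- substring(seq, starts + 1L, starts + 3L)
  hit <- win %in% codons
  data.frame(c_start = index_to_c(t, starts[hit]),
             codon = win[hit],
             canonical = win[hit] == "ATG")
}

#' Extend a TIS to its in-frame stop codon and classify the upORF
#'
#' Walks codon by codon from the TIS through the concatenated transcript
#' sequence until the first in-frame stop codon (TAA/TAG/TGA). The
#' resulting open reading frame is classified by where its stop lies:
#' \describe{
#'   \item{uORF}{stop codon entirely within the 5'UTR}
#'   \item{uoORF}{stop codon starts inside the CDS, before the main stop}
#'   \item{eCDS}{TIS in frame with the CDS; the ORF runs through the CDS
#'     and ends at the main stop codon (elongated CDS)}
#' }
#' Lengths include the stop codon. A TIS with no in-frame stop before the
#' transcript end (possible on truncated records without a 3'UTR) yields
#' `orf_type = "no_stop"` and is not an upORF.
#'
#' @param t A [transcript_model].
#' @param tis_c_start Coding position of the first TIS base (in the 5'UTR).
#' @param seq Optional sequence override (used internally to walk a
#'   variant-applied sequence); defaults to the reference sequence.
#' @return One-row data.frame: `tis_c_start`, `tis_codon`, `stop_c_start`,
#'   `stop_codon`, `orf_type`, `orf_len_nt`, `ends_at_main_stop`.
#' @examples
#' t <- transcript_model(utr5 = "ATGTAAC", cds = "ATGAAATGA")
#' extend_orf(t, -7)   # uORF, stop at c.-4, 6 nt
#' @export
extend_orf <- function(t, tis_c_start, seq = NULL) {
  stopifnot(inherits(t, "transcript_model"))
  if (is.null(seq)) seq <- t$seq
  tis_idx <- c_to_index(t, tis_c_start)
  if (tis_idx >= t$utr5_len)
    stop("TIS must start within the 5'UTR", call. = FALSE)
  codon <- tx_window(seq, tis_idx)
  n <- nchar(seq)
  main_stop_idx <- t$utr5_len + nchar(t$cds) - 3L
  idx <- tis_idx + 3L
  stop_idx <- NA_integer_
  while (idx + 2L <= n - 1L) {
    if (tx_window(seq, idx) %in% STOP_CODONS) { stop_idx <- idx; break }
    idx <- idx + 3L
  }
  if (is.na(stop_idx)) {
    return(data.frame(tis_c_start = tis_c_start, tis_codon = codon,
                      stop_c_start = NA_integer_, stop_codon = NA_character_,
                      orf_type = "no_stop", orf_len_nt = NA_integer_,
                      ends_at_main_stop = FALSE))
  }
  ends_main <- stop_idx == main_stop_idx
  type <- if (stop_idx + 2L < t$utr5_len) "uORF"
          else if (ends_main) "eCDS"
          else "uoORF"
  stop_c <- index_to_c(t, stop_idx)
  data.frame(tis_c_start = tis_c_start, tis_codon = codon,
             stop_c_start = stop_c,
             stop_codon = tx_window(seq, stop_idx),
             orf_type = type,
             orf_len_nt = c_distance(tis_c_start, index_to_c(t, stop_idx + 2L)),
             ends_at_main_stop = ends_main)
}

#' Reference upORF landscape of a transcript
#'
#' Applies [extend_orf()] to every TIS found by [scan_tis()] on the
#' reference sequence and deduplicates by (TIS, stop). This is the set of
#' upORFs already encoded by the transcript, against which variant-created
#' stop codons are linked and deletions of existing stops are resolved.
#'
#' @inheritParams scan_tis
#' @return data.frame of upORFs (see [extend_orf()] for columns), plus
#'   `tis_canonical`.
#' @export
reference_uporfs <- function(t, tis_mode = "both", region = NULL) {
  sites <- scan_tis(t, region = region, tis_mode = tis_mode)
  if (nrow(sites) == 0L)
    return(cbind(empty_orf_df(), tis_canonical = logical()))
  orfs <- do.call(rbind, lapply(sites$c_start, function(p) extend_orf(t, p)))
  orfs$tis_canonical <- sites$canonical
  orfs[!duplicated(orfs[c("tis_c_start", "stop_c_start")]), , drop = FALSE]
}

empty_orf_df <- function() {
  data.frame(tis_c_start = integer(), tis_codon = character(),
             stop_c_start = integer(), stop_codon = character(),
             orf_type = character(), orf_len_nt = integer(),
             ends_at_main_stop = logical())
}
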