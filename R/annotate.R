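#' Apply a single-nucleotide variant to the transcript sequence
#'
#' @param t A [transcript_model].
#' @param c_pos Coding position of the variant.
#' @param alt Alternate base.
#' @return The variant-applied concatenated sequence (character scalar).
#' @export
apply_snv <- function(t, c_pos, alt) {
  idx <- c_to_index(t, c_pos)
  seq <- t$seq
  substr(seq, idx + 1L, idx + 1L) <- alt
  seq
}

CONSEQUENCES <- c("uTIS_created", "uStop_created", "uStop_deleted")

#' Annotate one 5'UTR variant for upORF consequences
#'
#' Applies the alternate base and re-examines only the (at most) three
#' triplet windows — one per reading frame — that overlap the variant
#' position, for:
#' \describe{
#'   \item{uTIS_created}{a window that is a start codon (per `tis_mode`)
#'     on the variant sequence but carried a different codon on the
#'     reference; the new TIS is extended to its in-frame stop and the
#'     upORF typed (uORF / uoORF / eCDS) with its Kozak context read from
#'     the variant sequence.}
#'   \item{uStop_created}{a window that is TAA/TAG/TGA on the variant
#'     sequence but not on the reference, and is the first in-frame stop
#'     for at least one reference uTIS (one record per such uTIS). If
#'     that uTIS's reference ORF ended at a downstream stop the event is
#'     a shortening; if it ran to the main stop the new stop defines a
#'     new upORF.}
#'   \item{uStop_deleted}{a reference TAA/TAG/TGA window overlapping the
#'     variant that is no longer a stop on the variant sequence and
#'     terminated at least one reference upORF; each affected upORF is
#'     re-extended on the variant sequence (elongation). A change from
#'     one stop codon to another is not a deletion.}
#' }
#' A variant that destroys one TIS while creating another is reported for
#' the gain only; TIS loss is not an annotation class.
#'
#' @param t A [transcript_model].
#' @param snv One-row data.frame (`c_pos`, `ref`, `alt`), or an HGVS
#'   string such as `"c.-76C>T"`.
#' @param tis_mode See [tis_codons()]. Governs both TIS creation and the
#'   reference uTIS set used to link stop events.
#' @param report_orphan_stops If `TRUE`, stop codons created in a frame
#'   with no upstream reference uTIS are also reported (with `NA` TIS
#'   fields). Default `FALSE`: a stop with no upstream start changes no
#'   ORF.
#' @param ref A precomputed reference landscape from [ref_landscape()];
#'   computed on the fly when `NULL`.
#' @return data.frame of annotation records (zero rows when the variant
#'   changes nothing). Columns include the variant, consequence class,
#'   the anchoring TIS, the post-variant upORF, the affected reference
#'   ORF for stop events, and Kozak context.
#' @examples
#' t <- transcript_model(utr5 = "CCATGGTAACC", cds = "ATGAAATGA")
#' annotate_variant(t, "c.-5A>C")   # uStop_deleted: TAA -> CAA
#' @export
annotate_variant <- function(t, snv, tis_mode = "both",
                             report_orphan_stops = FALSE, ref = NULL) {
  if (is.character(snv)) {
    p <- parse_hgvs_c(snv)
    snv <- data.frame(c_pos = p$pos, ref = p$ref, alt = p$alt)
  }
  snv <- validate_snvs(t, snv)
  if (nrow(snv) != 1L) stop("annotate_variant() takes one variant", call. = FALSE)
  if (snv$c_pos > 0L)
    stop("variant must lie in the 5'UTR", call. = FALSE)
  if (is.null(ref)) ref <- ref_landscape(t, tis_mode)

  v <- c_to_index(t, snv$c_pos)
  alt_seq <- apply_snv(t, snv$c_pos, snv$alt)
  n <- nchar(t$seq)
  tis_set <- tis_codons(tis_mode)
  starts <- (v - 2L):v
  starts <- starts[starts >= 0L & starts + 2L <= n - 1L]
  ref_win <- substring(t$seq, starts + 1L, starts + 3L)
  alt_win <- substring(alt_seq, starts + 1L, starts + 3L)

  recs <- list()

  # --- TIS creation (windows must start in the 5'UTR; always true here) ---
  for (i in seq_along(starts)) {
    if (alt_win[i] %in% tis_set && alt_win[i] != ref_win[i]) {
      tis_c <- index_to_c(t, starts[i])
      orf <- extend_orf(t, tis_c, seq = alt_seq)
      koz <- kozak_context(t, tis_c, seq = alt_seq)
      recs[[length(recs) + 1L]] <- record_row(
        snv, "uTIS_created", tis_c, alt_win[i], alt_win[i] == "ATG",
        orf, koz)
    }
  }

  # --- stop creation ---
  for (i in seq_along(starts)) {
    if (alt_win[i] %in% STOP_CODONS && !(ref_win[i] %in% STOP_CODONS)) {
      s <- starts[i]
      linked <- linked_ref_tis(t, ref, s, alt_seq)
      if (nrow(linked) == 0L && report_orphan_stops) {
        orf <- stopgain_orf(t, NA_integer_, s, alt_seq)
        recs[[length(recs) + 1L]] <- record_row(
          snv, "uStop_created", NA_integer_, NA_character_, NA,
          orf, empty_kozak(), event_stop = index_to_c(t, s))
      }
      for (j in seq_len(nrow(linked))) {
        tis_c <- linked$c_start[j]
        orf <- stopgain_orf(t, tis_c, s, alt_seq)
        ref_orf <- ref$orfs[ref$orfs$tis_c_start == tis_c, , drop = FALSE]
        koz <- kozak_context(t, tis_c)
        recs[[length(recs) + 1L]] <- record_row(
          snv, "uStop_created", tis_c, linked$codon[j], linked$canonical[j],
          orf, koz, event_stop = index_to_c(t, s), ref_orf = ref_orf,
          stop_change = if (nrow(ref_orf) && isTRUE(ref_orf$ends_at_main_stop[1]))
            "new_uporf" else "shortening")
      }
    }
  }

  # --- stop deletion ---
  for (i in seq_along(starts)) {
    if (ref_win[i] %in% STOP_CODONS && !(alt_win[i] %in% STOP_CODONS)) {
      s <- starts[i]
      stop_c <- index_to_c(t, s)
      affected <- ref$orfs[!is.na(ref$orfs$stop_c_start) &
                             ref$orfs$stop_c_start == stop_c, , drop = FALSE]
      for (j in seq_len(nrow(affected))) {
        tis_c <- affected$tis_c_start[j]
        orf <- extend_orf(t, tis_c, seq = alt_seq)
        koz <- kozak_context(t, tis_c)
        recs[[length(recs) + 1L]] <- record_row(
          snv, "uStop_deleted", tis_c, affected$tis_codon[j],
          affected$tis_codon[j] == "ATG", orf, koz,
          event_stop = stop_c, ref_orf = affected[j, , drop = FALSE])
      }
    }
  }

  if (length(recs) == 0L) return(empty_records())
  do.call(rbind, recs)
}

#' Precompute the reference TIS and upORF landscape
#'
#' @inheritParams annotate_variant
#' @return list with `tis` (from [scan_tis()]) and `orfs`
#'   (from [reference_uporfs()]), both on the full 5'UTR.
#' @export
ref_landscape <- function(t, tis_mode = "both") {
  tis <- scan_tis(t, tis_mode = tis_mode)
  orfs <- reference_uporfs(t, tis_mode = tis_mode)
  tis$idx <- c_to_index(t, tis$c_start)
  list(tis = tis, orfs = orfs)
}

# reference uTIS upstream of stop window s, in frame, for which s is the
# first in-frame stop on the variant-applied sequence
linked_ref_tis <- function(t, ref, s, alt_seq) {
  cand <- ref$tis[ref$tis$idx + 3L <= s & (s - ref$tis$idx) %% 3L == 0L, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  keep <- vapply(cand$idx, function(ti) {
    idx <- ti + 3L
    while (idx < s) {
      if (tx_window(alt_seq, idx) %in% STOP_CODONS) return(FALSE)
      idx <- idx + 3L
    }
    TRUE
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# ORF row for a created stop at window s anchored at tis_c (or orphan NA)
stopgain_orf <- function(t, tis_c, s, alt_seq) {
  stop_c <- index_to_c(t, s)
  L <- t$utr5_len
  main_stop_idx <- L + nchar(t$cds) - 3L
  type <- if (s + 2L < L) "uORF" else if (s == main_stop_idx) "eCDS" else "uoORF"
  data.frame(
    tis_c_start = tis_c, tis_codon = NA_character_,
    stop_c_start = stop_c, stop_codon = tx_window(alt_seq, s),
    orf_type = if (is.na(tis_c)) NA_character_ else type,
    orf_len_nt = if (is.na(tis_c)) NA_integer_
                 else c_distance(tis_c, index_to_c(t, s + 2L)),
    ends_at_main_stop = s == main_stop_idx)
}

empty_kozak <- function() {
  data.frame(kozak_7mer = NA_character_, minus3 = NA_character_,
             plus4 = NA_character_, kozak_class = NA_character_,
             kozak_determined = NA)
}

record_row <- function(snv, consequence, tis_c, tis_codon, tis_canonical,
                       orf, koz, event_stop = NA_integer_, ref_orf = NULL,
                       stop_change = NA_character_) {
  data.frame(
    hgvs_c = snv$hgvs_c, c_pos = snv$c_pos, ref = snv$ref, alt = snv$alt,
    consequence = consequence,
    tis_c_start = tis_c, tis_codon = tis_codon, tis_canonical = tis_canonical,
    stop_c_start = orf$stop_c_start[1], stop_codon = orf$stop_codon[1],
    orf_type = orf$orf_type[1], orf_len_nt = orf$orf_len_nt[1],
    ends_at_main_stop = orf$ends_at_main_stop[1],
    event_stop_c_start = event_stop,
    ref_stop_c_start = if (!is.null(ref_orf) && nrow(ref_orf))
      ref_orf$stop_c_start[1] else NA_integer_,
    ref_orf_type = if (!is.null(ref_orf) && nrow(ref_orf))
      ref_orf$orf_type[1] else NA_character_,
    ref_orf_len_nt = if (!is.null(ref_orf) && nrow(ref_orf))
      ref_orf$orf_len_nt[1] else NA_integer_,
    stop_change = stop_change,
    kozak_7mer = koz$kozak_7mer[1], kozak_class = koz$kozak_class[1],
    kozak_determined = koz$kozak_determined[1])
}

empty_records <- function() {
  data.frame(
    hgvs_c = character(), c_pos = integer(), ref = character(),
    alt = character(), consequence = character(), tis_c_start = integer(),
    tis_codon = character(), tis_canonical = logical(),
    stop_c_start = integer(), stop_codon = character(),
    orf_type = character(), orf_len_nt = integer(),
    ends_at_main_stop = logical(), event_stop_c_start = integer(),
    ref_stop_c_start = integer(), ref_orf_type = character(),
    ref_orf_len_nt = integer(), stop_change = character(),
    kozak_7mer = character(), kozak_class = character(),
    kozak_determined = logical())
}

#' Resolve the deletion of an upORF's stop codon by a variant
#'
#' Checks that `snv` destroys the stop codon terminating `ref_uporf`
#' (a change from one stop codon to another is not a deletion) and, when
#' it does, re-extends the upORF from its TIS on the variant-applied
#' sequence.
#'
#' @param t A [transcript_model].
#' @param snv One-row variant data.frame or HGVS string.
#' @param ref_uporf One row of [reference_uporfs()] output.
#' @return A one-row record (as in [annotate_variant()]) or a zero-row
#'   data.frame when the stop is not deleted.
#' @export
resolve_stop_deletion <- function(t, snv, ref_uporf) {
  recs <- annotate_variant(t, snv)
  recs[recs$consequence == "uStop_deleted" &
         !is.na(recs$tis_c_start) &
         recs$tis_c_start == ref_uporf$tis_c_start[1] &
         recs$event_stop_c_start == ref_uporf$stop_c_start[1], , drop = FALSE]
}
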