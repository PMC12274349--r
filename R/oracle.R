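#' Brute-force variant annotation oracle
#'
#' An independent re-implementation of the annotation semantics used to
#' property-test [annotate_variant()]. Instead of re-examining only the
#' windows overlapping the variant, it scans EVERY triplet window of the
#' reference and of the variant-applied sequence in all three frames,
#' builds the complete TIS and stop landscapes of both, and classifies
#' the set differences with its own coordinate, ORF-typing and Kozak
#' code (no shared ORF-walking internals). Slower by design; test-only.
#'
#' @inheritParams annotate_variant
#' @return data.frame with the comparable record fields: `hgvs_c`,
#'   `consequence`, `tis_c_start`, `tis_codon`, `stop_c_start`,
#'   `orf_type`, `orf_len_nt`, `event_stop_c_start`, `ref_stop_c_start`,
#'   `kozak_7mer`, `kozak_class`.
#' @export
brute_force_annotate <- function(t, snv, tis_mode = "both") {
  if (is.character(snv)) {
    p <- parse_hgvs_c(snv)
    snv <- data.frame(c_pos = p$pos, ref = p$ref, alt = p$alt)
  }
  stopifnot(nrow(snv) == 1L, snv$c_pos < 0L)
  L <- t$utr5_len
  n <- nchar(t$seq)
  v <- L + snv$c_pos                     # own coordinate arithmetic
  stopifnot(substr(t$seq, v + 1L, v + 1L) == snv$ref)
  alt_seq <- t$seq
  substr(alt_seq, v + 1L, v + 1L) <- snv$alt
  hgvs <- paste0("c.", snv$c_pos, snv$ref, ">", snv$alt)

  stops <- c("TAA", "TAG", "TGA")
  tset <- switch(tis_mode,
                 canonical = "ATG",
                 near_cognate = c("CTG", "GTG", "TTG", "ACG", "AAG", "AGG",
                                  "ATA", "ATC", "ATT"),
                 both = c("ATG", "CTG", "GTG", "TTG", "ACG", "AAG", "AGG",
                          "ATA", "ATC", "ATT"),
                 stop("unknown tis_mode"))

  landscape <- function(seq) {
    starts <- 0:(n - 3L)
    codons <- substring(seq, starts + 1L, starts + 3L)
    list(starts = starts, codons = codons,
         tis = starts[starts < L & codons %in% tset],
         stop = starts[codons %in% stops])
  }
  ref_ls <- landscape(t$seq)
  alt_ls <- landscape(alt_seq)

  first_stop <- function(ls, from) {
    s <- ls$stop[ls$stop >= from + 3L & (ls$stop - from) %% 3L == 0L]
    if (length(s)) min(s) else NA_integer_
  }
  to_c <- function(i) ifelse(i >= L, i - L + 1L, i - L)
  main_stop <- L + nchar(t$cds) - 3L
  orf_of <- function(ls, tis, seq) {
    s <- first_stop(ls, tis)
    if (is.na(s))
      return(list(stop_c = NA_integer_, type = "no_stop", len = NA_integer_))
    type <- if (s + 2L < L) "uORF" else if (s == main_stop) "eCDS" else "uoORF"
    len <- (s + 2L) - tis + 1L           # index span == inclusive nt count
    list(stop_c = to_c(s), type = type, len = len)
  }
  koz <- function(seq, tis) {
    lo <- tis - 3L
    sevenmer <- paste0(strrep("N", max(0L, -lo)),
                       substr(seq, max(0L, lo) + 1L, tis + 4L))
    if (nchar(sevenmer) < 7L)
      sevenmer <- paste0(sevenmer, strrep("N", 7L - nchar(sevenmer)))
    m3 <- substr(sevenmer, 1L, 1L); p4 <- substr(sevenmer, 7L, 7L)
    cls <- if (m3 == "N" || p4 == "N") "weak"
           else if (m3 %in% c("A", "G") && p4 == "G") "strong"
           else if (m3 %in% c("A", "G") || p4 == "G") "moderate"
           else "weak"
    list(sevenmer = sevenmer, cls = cls)
  }
  row <- function(consequence, tis, codon, orf, kz,
                  event_stop = NA_integer_, ref_stop = NA_integer_) {
    data.frame(hgvs_c = hgvs, consequence = consequence,
               tis_c_start = if (is.na(tis)) NA_integer_ else to_c(tis),
               tis_codon = codon, stop_c_start = orf$stop_c,
               orf_type = orf$type, orf_len_nt = orf$len,
               event_stop_c_start = event_stop, ref_stop_c_start = ref_stop,
               kozak_7mer = kz$sevenmer, kozak_class = kz$cls)
  }

  out <- list()

  ref_pairs <- paste(ref_ls$tis, ref_ls$codons[ref_ls$tis + 1L])
  alt_pairs <- paste(alt_ls$tis, alt_ls$codons[alt_ls$tis + 1L])
  for (p in setdiff(alt_pairs, ref_pairs)) {
    tis <- as.integer(strsplit(p, " ")[[1]][1])
    codon <- strsplit(p, " ")[[1]][2]
    out[[length(out) + 1L]] <-
      row("uTIS_created", tis, codon, orf_of(alt_ls, tis, alt_seq),
          koz(alt_seq, tis))
  }

  new_stops <- setdiff(alt_ls$stop, ref_ls$stop)
  for (s in new_stops) {
    for (tis in ref_ls$tis) {
      if (tis + 3L <= s && (s - tis) %% 3L == 0L &&
          identical(first_stop(alt_ls, tis), s)) {
        ref_orf <- orf_of(ref_ls, tis, t$seq)
        out[[length(out) + 1L]] <-
          row("uStop_created", tis, ref_ls$codons[tis + 1L],
              orf_of(alt_ls, tis, alt_seq), koz(t$seq, tis),
              event_stop = to_c(s), ref_stop = ref_orf$stop_c)
      }
    }
  }

  lost_stops <- setdiff(ref_ls$stop, alt_ls$stop)
  for (s in lost_stops) {
    for (tis in ref_ls$tis) {
      if (identical(first_stop(ref_ls, tis), s)) {
        out[[length(out) + 1L]] <-
          row("uStop_deleted", tis, ref_ls$codons[tis + 1L],
              orf_of(alt_ls, tis, alt_seq), koz(t$seq, tis),
              event_stop = to_c(s), ref_stop = to_c(s))
      }
    }
  }

  if (length(out) == 0L)
    return(data.frame(hgvs_c = character(), consequence = character(),
                      tis_c_start = integer(), tis_codon = character(),
                      stop_c_start = integer(), orf_type = character(),
                      orf_len_nt = integer(), event_stop_c_start = integer(),
                      ref_stop_c_start = integer(), kozak_7mer = character(),
                      kozak_class = character()))
  res <- do.call(rbind, out)
  res[order(res$consequence, res$tis_c_start, res$event_stop_c_start,
            method = "radix"), , drop = FALSE]
}
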