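# shared fixtures and comparison helpers

# tiny hand-checkable transcript: uACG at c.-7, uATG at c.-4 (junction-spanning
# windows read into the CDS)
toy_acg_atg <- function() transcript_model(utr5 = "ACGATGC", cds = "ATGAAATGA")

# 5'UTR carrying a complete uORF (ATG..TAA) ahead of a short CDS
toy_uorf <- function(stop = "TAA")
  transcript_model(utr5 = paste0("CCATGAAA", stop, "CC"), cds = "ATGAAACCCTGA")

# all-C 5'UTR: no single substitution can create a start or stop codon,
# and there is nothing to delete
toy_inert <- function() transcript_model(utr5 = "CCCCCC", cds = "ATGAAATGA")

CMP_COLS <- c("hgvs_c", "consequence", "tis_c_start", "tis_codon",
              "stop_c_start", "orf_type", "orf_len_nt", "event_stop_c_start",
              "ref_stop_c_start", "kozak_7mer", "kozak_class")

norm_records <- function(d) {
  d <- d[, CMP_COLS, drop = FALSE]
  d <- d[order(d$consequence, d$tis_c_start, d$event_stop_c_start,
               method = "radix"), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# annotate every 5'UTR SNV of t with both the windowed annotator and the
# brute-force oracle; TRUE when all record sets agree
oracle_agrees <- function(t, tis_mode = "both") {
  ref <- ref_landscape(t, tis_mode)
  snvs <- enumerate_snvs(t)
  for (i in seq_len(nrow(snvs))) {
    a <- norm_records(annotate_variant(t, snvs[i, ], tis_mode = tis_mode,
                                       ref = ref))
    b <- norm_records(brute_force_annotate(t, snvs[i, ], tis_mode = tis_mode))
    if (!isTRUE(all.equal(a, b, check.attributes = FALSE)))
      return(snvs$hgvs_c[i])
  }
  TRUE
}

# count of the 9 single-base substitutions of a planted uORF stop codon
# that the annotator reports as deleting it
count_stop_deleters <- function(stop) {
  t <- toy_uorf(stop)
  stop_c <- -5L  # first base of the planted stop codon
  n_del <- 0L
  for (off in 0:2) {
    pos <- stop_c + off
    ref <- substr(t$utr5, t$utr5_len + pos + 1L, t$utr5_len + pos + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      r <- annotate_variant(t, data.frame(c_pos = pos, ref = ref, alt = alt))
      if (any(r$consequence == "uStop_deleted" & r$event_stop_c_start == stop_c))
        n_del <- n_del + 1L
    }
  }
  n_del
}
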