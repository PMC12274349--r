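#' Build the saturation upORF-annotation catalog
#'
#' Runs [enumerate_snvs()] over the region and [annotate_variant()] on
#' every variant, then aggregates the records into summary tallies:
#' per-consequence pure classes, multi-consequence variants (at least two
#' distinct consequence classes on the same SNV), upORF type counts for
#' TIS-created ORFs, and the stop-position landscape.
#'
#' @inheritParams annotate_variant
#' @param region See [enumerate_snvs()].
#' @return An object of class `uporf_catalog`: list with `transcript_id`,
#'   `tis_mode`, `region`, `n_snvs`, `records` (data.frame) and `summary`
#'   (list of counts, see [summary.uporf_catalog()]).
#' @examples
#' t <- transcript_model(utr5 = "GGCACCATGGTAACCGG", cds = "ATGGCAAAATGA")
#' cat9 <- build_catalog(t)
#' summary(cat9)
#' @export
build_catalog <- function(t, region = NULL, tis_mode = "both",
                          report_orphan_stops = FALSE) {
  stopifnot(inherits(t, "transcript_model"))
  region <- resolve_utr_region(t, region)
  snvs <- enumerate_snvs(t, region)
  ref <- ref_landscape(t, tis_mode)
  recs <- vector("list", nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    recs[[i]] <- annotate_variant(t, snvs[i, , drop = FALSE],
                                  tis_mode = tis_mode,
                                  report_orphan_stops = report_orphan_stops,
                                  ref = ref)
  }
  records <- do.call(rbind, c(recs, list(empty_records())))
  rownames(records) <- NULL
  structure(
    list(transcript_id = t$id, tis_mode = tis_mode, region = region,
         n_snvs = nrow(snvs), records = records,
         summary = catalog_summary(records, nrow(snvs))),
    class = "uporf_catalog")
}

catalog_summary <- function(records, n_snvs) {
  classes <- split(records$consequence, records$hgvs_c)
  n_classes <- vapply(classes, function(x) length(unique(x)), integer(1))
  pure <- vapply(classes[n_classes == 1L], function(x) x[1], character(1))
  utis <- records[records$consequence == "uTIS_created", , drop = FALSE]
  utis_orfs <- utis[!is.na(utis$orf_type) & utis$orf_type != "no_stop", ,
                    drop = FALSE]
  stop_tally <- if (nrow(utis_orfs))
    table(orf_type = utis_orfs$orf_type,
          stop = ifelse(utis_orfs$ends_at_main_stop, "main",
                        as.character(utis_orfs$stop_c_start)))
  else table(character())
  list(
    n_snvs = n_snvs,
    n_annotated = length(classes),
    n_records = nrow(records),
    n_uporfs = sum(!is.na(records$orf_len_nt)),
    n_pure_uTIS = sum(pure == "uTIS_created"),
    n_pure_uStop_new = sum(pure == "uStop_created"),
    n_pure_uStop_del = sum(pure == "uStop_deleted"),
    n_multi = sum(n_classes >= 2L),
    n_uTIS_snvs = length(unique(utis$hgvs_c)),
    n_uTIS_uporfs = nrow(utis_orfs),
    n_uORF = sum(utis_orfs$orf_type == "uORF"),
    n_uoORF = sum(utis_orfs$orf_type == "uoORF"),
    n_eCDS = sum(utis_orfs$orf_type == "eCDS"),
    stop_positions = stop_tally)
}

#' @export
print.uporf_catalog <- function(x, ...) {
  s <- x$summary
  cat(sprintf("upORF saturation catalog for '%s' (tis_mode = %s)\n",
              x$transcript_id, x$tis_mode))
  cat(sprintf("  region c.%d..c.%d: %d SNVs, %d annotated, %d upORFs\n",
              x$region[1], x$region[2], s$n_snvs, s$n_annotated, s$n_uporfs))
  invisible(x)
}

#' Summarise a upORF saturation catalog
#'
#' @param object A `uporf_catalog`.
#' @param ... Unused.
#' @return The summary count list, invisibly; printed in a compact layout.
#' @export
summary.uporf_catalog <- function(object, ...) {
  s <- object$summary
  cat(sprintf("Saturation of '%s', c.%d..c.%d (tis_mode = %s)\n",
              object$transcript_id, object$region[1], object$region[2],
              object$tis_mode))
  cat(sprintf("  SNVs enumerated:            %d\n", s$n_snvs))
  cat(sprintf("  SNVs annotated:             %d\n", s$n_annotated))
  cat(sprintf("    creating uTIS only:       %d\n", s$n_pure_uTIS))
  cat(sprintf("    creating uStop only:      %d\n", s$n_pure_uStop_new))
  cat(sprintf("    deleting uStop only:      %d\n", s$n_pure_uStop_del))
  cat(sprintf("    multiple consequences:    %d\n", s$n_multi))
  cat(sprintf("  upORFs across records:      %d\n", s$n_uporfs))
  cat(sprintf("  uTIS-created SNVs/upORFs:   %d / %d\n",
              s$n_uTIS_snvs, s$n_uTIS_uporfs))
  cat(sprintf("    uORF / uoORF / eCDS:      %d / %d / %d\n",
              s$n_uORF, s$n_uoORF, s$n_eCDS))
  if (length(s$stop_positions)) {
    cat("  stop-position landscape (uTIS-created):\n")
    print(s$stop_positions)
  }
  invisible(s)
}

#' Plot the upORF landscape of a catalog
#'
#' Barplot of TIS-created upORF counts by stop position, split by upORF
#' type — the stop-codon landscape of the saturated 5'UTR.
#'
#' @param x A `uporf_catalog`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.uporf_catalog <- function(x, ...) {
  tally <- x$summary$stop_positions
  if (length(tally) == 0L) {
    warning("catalog has no TIS-created upORFs to plot")
    return(invisible(NULL))
  }
  graphics::barplot(as.matrix(tally), beside = TRUE,
                    legend.text = rownames(tally),
                    xlab = "stop codon position (first base, c.)",
                    ylab = "upORFs created by uTIS-SNVs",
                    main = x$transcript_id, ...)
  invisible(x)
}

CATALOG_TSV_COLS <- c("hgvs_c", "ref", "alt", "consequence", "tis_codon",
                      "tis_c_start", "stop_c_start", "orf_type", "orf_len_nt",
                      "kozak_7mer", "kozak_class", "event_stop_c_start",
                      "ref_stop_c_start", "ref_orf_type", "ref_orf_len_nt",
                      "stop_change")

#' Write a catalog as TSV and annotated VCF
#'
#' The TSV carries one row per annotation record. The VCF carries one
#' line per annotated SNV, with the per-record fields pipe-delimited and
#' comma-joined in the `UTRSAT_CSQ` INFO key
#' (`consequence|tis_codon|tis_c_start|stop_c_start|orf_type|orf_len_nt|kozak_7mer|kozak_class`).
#' Ordering is deterministic: position, then alternate base, then record
#' order.
#'
#' @param catalog A `uporf_catalog`.
#' @param t The [transcript_model] it was built from.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.vcf`.
#' @return Invisibly, the two paths written.
#' @export
write_catalog <- function(catalog, t, prefix) {
  stopifnot(inherits(catalog, "uporf_catalog"))
  r <- catalog$records
  ord <- order(r$c_pos, r$alt)
  r <- r[ord, , drop = FALSE]
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(r[, CATALOG_TSV_COLS, drop = FALSE], tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vcf <- paste0(prefix, ".vcf")
  if (nrow(r)) {
    csq_fields <- c("consequence", "tis_codon", "tis_c_start", "stop_c_start",
                    "orf_type", "orf_len_nt", "kozak_7mer", "kozak_class")
    per_rec <- apply(r[, csq_fields, drop = FALSE], 1L, function(z)
      paste(ifelse(is.na(z), "", trimws(z)), collapse = "|"))
    key <- paste0(r$c_pos, r$alt)
    snv <- r[!duplicated(key), c("c_pos", "ref", "alt"), drop = FALSE]
    info <- vapply(split(per_rec, factor(key, levels = unique(key))),
                   paste, character(1), collapse = ",")
    write_vcf(snv, t, vcf,
              info = paste0("UTRSAT_CSQ=", info),
              extra_headers = paste0(
                "##INFO=<ID=UTRSAT_CSQ,Number=.,Type=String,Description=",
                "\"upORF consequence: ", paste(csq_fields, collapse = "|"),
                "\">"))
  } else {
    write_vcf(data.frame(c_pos = integer(), ref = character(),
                         alt = character())[0, ], t, vcf)
  }
  invisible(c(tsv = tsv, vcf = vcf))
}

#' @rdname write_catalog
#' @param path Path to a TSV written by `write_catalog()`.
#' @return `read_catalog_tsv()`: the records data.frame.
#' @export
read_catalog_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(hgvs_c = "character"),
                    stringsAsFactors = FALSE)
}
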