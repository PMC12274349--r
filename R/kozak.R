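#' Kozak context extraction and strength classification
#'
#' The Kozak context of a TIS is summarised as the 7-mer covering positions
#' -3..-1, the TIS triplet, and +4 (position +1 being the first TIS base).
#' Strength uses the two dominant positions only:
#' \describe{
#'   \item{strong}{purine (A/G) at -3 AND G at +4}
#'   \item{moderate}{exactly one of the two}
#'   \item{weak}{neither}
#' }
#' For variant-created TIS the context must be read from the
#' variant-applied sequence, since the variant may itself sit inside the
#' 7-mer.
#'
#' @param t A [transcript_model].
#' @param tis_c_start Coding position of the first TIS base.
#' @param seq Optional sequence override (variant-applied sequence).
#' @return One-row data.frame: `kozak_7mer`, `minus3`, `plus4`,
#'   `kozak_class`, `kozak_determined`. When fewer than 3 bases precede
#'   the TIS the 7-mer is N-padded, `kozak_determined` is `FALSE` and the
#'   class falls back to `"weak"`.
#' @examples
#' t <- transcript_model(utr5 = "CACGCTGGA", cds = "ATGAAATGA")
#' kozak_context(t, -8)   # ACGCTGG -> strong
#' @export
kozak_context <- function(t, tis_c_start, seq = NULL) {
  stopifnot(inherits(t, "transcript_model"))
  if (is.null(seq)) seq <- t$seq
  idx <- c_to_index(t, tis_c_start)
  up <- idx - 3L
  pad <- 0L
  if (up < 0L) { pad <- -up; up <- 0L }
  raw <- substr(seq, up + 1L, idx + 4L)
  sevenmer <- paste0(strrep("N", pad), raw)
  if (nchar(sevenmer) < 7L)  # TIS too close to the 3' end for a +4 base
    sevenmer <- paste0(sevenmer, strrep("N", 7L - nchar(sevenmer)))
  minus3 <- substr(sevenmer, 1L, 1L)
  plus4 <- substr(sevenmer, 7L, 7L)
  determined <- minus3 != "N" && plus4 != "N"
  data.frame(kozak_7mer = sevenmer, minus3 = minus3, plus4 = plus4,
             kozak_class = if (determined) kozak_class(sevenmer) else "weak",
             kozak_determined = determined)
}

#' @rdname kozak_context
#' @param sevenmer A 7-base Kozak context string (or vector of them).
#' @export
kozak_class <- function(sevenmer) {
  minus3 <- substr(sevenmer, 1L, 1L)
  plus4 <- substr(sevenmer, 7L, 7L)
  pur <- minus3 %in% c("A", "G")
  g4 <- plus4 == "G"
  ifelse(pur & g4, "strong", ifelse(pur | g4, "moderate", "weak"))
}

#' Tally Kozak strength classes
#'
#' @param x A character vector of 7-mers, or a data.frame with a
#'   `kozak_7mer` column (e.g. catalog records).
#' @return Named integer vector with counts for strong, moderate, weak.
#' @examples
#' classify_table(c("ACGCTGG", "CAGATGG", "CATATGC"))
#' @export
classify_table <- function(x) {
  if (is.data.frame(x)) x <- x$kozak_7mer
  x <- x[!is.na(x)]
  cls <- factor(kozak_class(x), levels = c("strong", "moderate", "weak"))
  out <- table(cls)
  structure(as.integer(out), names = names(out))
}
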