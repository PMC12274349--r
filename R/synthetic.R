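#' Seeded random transcript generator
#'
#' Builds a reproducible random [transcript_model] for testing: a random
#' 5'UTR, a CDS assembled from random non-stop codons between ATG and a
#' random stop codon (hence never containing an internal in-frame stop),
#' and optional planted motifs. Planting is a substitution of `motif`
#' starting at 1-based `offset` into the concatenated 5'UTR + CDS; the
#' model is re-validated afterwards, so a planting that corrupts the CDS
#' (e.g. an in-frame stop) is a generation error.
#'
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param utr5_len 5'UTR length (>= 1).
#' @param cds_codons Number of CDS codons including start and stop (>= 2).
#' @param planted Optional list of `list(offset, motif)` substitutions.
#' @param id Transcript identifier.
#' @return A [transcript_model].
#' @examples
#' t <- random_transcript(seed = 1, utr5_len = 30, cds_codons = 10)
#' identical(t$seq, random_transcript(1, 30, 10)$seq)  # TRUE
#' @export
random_transcript <- function(seed, utr5_len = 60L, cds_codons = 20L,
                              planted = NULL, id = NULL) {
  stopifnot(utr5_len >= 1L, cds_codons >= 2L)
  if (is.null(id)) id <- sprintf("toy_seed%d", seed)
  seq <- withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    utr5 <- paste(sample(bases, utr5_len, replace = TRUE), collapse = "")
    body <- if (cds_codons > 2L)
      paste(sample(NON_STOP_CODONS, cds_codons - 2L, replace = TRUE),
            collapse = "")
    else ""
    paste0(utr5, "ATG", body, sample(STOP_CODONS, 1L))
  })
  for (p in planted) {
    off <- as.integer(p[[1]]); motif <- toupper(p[[2]])
    if (off < 1L || off + nchar(motif) - 1L > nchar(seq))
      stop("planted motif falls outside the transcript", call. = FALSE)
    substr(seq, off, off + nchar(motif) - 1L) <- motif
  }
  tryCatch(
    transcript_model(utr5 = substr(seq, 1L, utr5_len),
                     cds = substr(seq, utr5_len + 1L, nchar(seq)),
                     id = id),
    error = function(e)
      stop(sprintf("planted motifs broke transcript validity: %s",
                   conditionMessage(e)), call. = FALSE))
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Synthetic ENG-like transcript
#'
#' A deterministic synthetic stand-in emulating the upORF landscape of
#' the ENG MANE transcript: a 303-nt 5'UTR ahead of a 1977-nt CDS
#' (659 codons, stop included, like the long Endoglin isoform). It is NOT
#' the ENG sequence; only the documented landscape features are embedded:
#' \itemize{
#'   \item the local reference context of the 14 characterised
#'     uTIS-creating variants (c.-287C>A, c.-271G>T, c.-249C>G,
#'     c.-182C>A, c.-167C>A, c.-142A>T, c.-127C>T, c.-79C>T, c.-76C>T,
#'     c.-68G>A, c.-37G>T, c.-33A>G, c.-31G>T, c.-10C>T), so each
#'     recreates its published uTIS codon, Kozak 7-mer and upORF size;
#'   \item the shared uoORF stop codon with first base at c.125, and a
#'     second in-CDS stop at c.90 in the other overlapping frame;
#'   \item fully-upstream stop codons TGA at c.-166 and TAA at c.-34,
#'     each terminating a planted reference uAUG (so stop-deletion
#'     elongates c.-166-ORFs to c.-34 and c.-34-ORFs to c.90);
#'   \item a strong-Kozak main ATG.
#' }
#' Unconstrained positions are seeded random filler, repaired so that no
#' unintended stop codon interrupts the engineered reading frames; global
#' saturation counts on this construct are therefore NOT comparable to
#' the real transcript.
#'
#' @return A [transcript_model] with id `"ENG_synthetic"`.
#' @export
synthetic_eng_like <- function() {
  L <- 303L
  cds_codons <- 659L
  rnd <- withr::with_seed(197703L, list(
    utr = sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(.15, .35, .35, .15)),
    codons = sample(NON_STOP_CODONS, cds_codons, replace = TRUE)))
  utr <- rnd$utr

  # reference contexts of the characterised variants (0-based start, bases);
  # overlapping segments were cross-checked for agreement before merging
  segs <- list(
    list(13L,  "CATCTGC"),       # c.-287C>A -> CATATGC (uATG; also uATA)
    list(28L,  "GCCAGGA"),       # c.-271G>T -> GCCATGA (uATG; also TGA gain)
    list(49L,  "GCCATCC"),       # c.-249C>G -> GCCATGC
    list(104L, "ATG"),           # reference uAUG ending at the c.-166 stop
    list(118L, "TCCCTGT"),       # c.-182C>A -> TCCATGT
    list(133L, "CTCCTGA"),       # c.-167C>A -> CTCATGA; TGA = stop c.-166
    list(157L, "CAGAAGG"),       # c.-142A>T -> CAGATGG
    list(172L, "GGGACGC"),       # c.-127C>T -> GGGATGC
    list(182L, "ATG"),           # reference uAUG ending at the c.-34 stop
    list(220L, "CCCACGCCGG"),    # c.-79C>T -> CCCATGC; c.-76C>T -> ACGCTGG
    list(232L, "CCGGTGC"),       # c.-68G>A -> CCGATGC
    list(262L, "CACAGGATAAGGC"), # c.-37G>T, c.-33A>G, c.-31G>T; TAA = c.-34
    list(289L, "CCCACGT"),       # c.-10C>T -> CCCATGT
    list(300L, "ACC"))           # -3..-1 of the main ATG (strong Kozak)
  planted_utr <- logical(L)
  for (s in segs) {
    i <- s[[1]] + seq_len(nchar(s[[2]])) - 1L
    utr[i + 1L] <- strsplit(s[[2]], "")[[1]]
    planted_utr[i + 1L] <- TRUE
  }

  codons <- rnd$codons
  codons[1:2] <- c("ATG", "GCC")
  codons[30:31] <- c("CAT", "AAC")   # TAA spanning codons, first base c.90
  codons[42:43] <- c("CTG", "AAC")   # TGA spanning codons, first base c.125
  codons[cds_codons] <- "TGA"
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
  planted_cds <- logical(length(cds))
  planted_cds[c(1:6, 88:93, 124:129,
                (length(cds) - 2L):length(cds))] <- TRUE

  chars <- c(utr, cds)
  planted <- c(planted_utr, planted_cds)

  # repair filler: the engineered frames must stay free of stray stops.
  # Replacing one unplanted base of an offending window with C always
  # destroys the stop (no stop codon contains C) and can create none.
  f1 <- seq(16L, 424L, by = 3L)                       # frame of the c.125 stop
  f2 <- setdiff(seq(2L, 389L, by = 3L), c(137L, 269L)) # frame of c.-166/-34/90
  repeat {
    win <- vapply(c(f1, f2), function(i)
      paste(chars[(i + 1L):(i + 3L)], collapse = ""), character(1))
    bad <- c(f1, f2)[win %in% STOP_CODONS]
    if (length(bad) == 0L) break
    for (i in bad) {
      j <- ((i + 1L):(i + 3L))
      j <- j[!planted[j]][1]
      chars[j] <- "C"
    }
  }

  transcript_model(utr5 = paste(chars[1:L], collapse = ""),
                   cds = paste(chars[(L + 1L):length(chars)], collapse = ""),
                   id = "ENG_synthetic")
}
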