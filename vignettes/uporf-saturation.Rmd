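---
title: "Saturation annotation of upORF-altering 5'UTR variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation annotation of upORF-altering 5'UTR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfsat)
```

## The problem

Upstream open reading frames (upORFs) are translation units initiating in
the 5'UTR of an mRNA. A single-nucleotide variant (SNV) in the 5'UTR can
create a new upstream translation initiation site (uTIS) — the canonical
AUG or one of the nine near-cognate codons differing from AUG at one
position — create a new upstream stop codon, or delete an existing one.
Each such event reshapes the upORF landscape of the transcript and can
repress translation of the main coding sequence. In *ENG* (Endoglin),
whose loss of function causes Hereditary Hemorrhagic Telangiectasia,
5'UTR variants creating uAUG- or uCUG-initiated overlapping upORFs that
terminate at the in-CDS stop codon at c.125 reduce protein levels and are
clinically relevant; this motivates exhaustive, *a priori* annotation of
every possible 5'UTR SNV rather than waiting for variants to be observed.

`uorfsat` implements that saturation analysis for any single-isoform
transcript model: enumerate all `3 × L` SNVs of an `L`-nt 5'UTR, classify
each as uTIS-creating, uStop-creating and/or uStop-deleting, resolve
every event to a concrete upORF, and aggregate a catalog.

## Coordinates and conventions

All positions are HGVS coding-DNA (c.) positions: c.1 is the A of the
main AUG, c.-1 the base 5' of it, and there is no position zero.
`c_to_index()` / `index_to_c()` convert to zero-based offsets in the
concatenated 5'UTR + CDS (+ 3'UTR) sequence and are bijective on the
transcript; `c_distance()` counts nucleotides inclusively, skipping the
nonexistent zero.

Two conventions are fixed package-wide because they make the published
upORF arithmetic internally consistent:

* a stop codon "at position c.X" means the codon whose **first** base is
  c.X (so the stop at c.125 occupies c.125–c.127);
* upORF length **includes** the stop codon. Hence an upORF started at
  c.-77 and terminated by the stop at c.125 is
  `c_distance(-77, 127) = 204` nt, and every upORF in frame with that
  stop has length `|uTIS start| + 127`.

## The annotation model

A transcript is a validated `transcript_model`: the CDS must begin with
ATG, end with TAA/TAG/TGA, have length a multiple of 3 and carry no
internal in-frame stop. That last invariant is what guarantees that any
uTIS in frame with the CDS necessarily runs through to the main stop
codon (an elongated CDS, eCDS).

`extend_orf()` walks codons from a uTIS to the first in-frame stop and
classifies by where that stop lies: entirely inside the 5'UTR (uORF),
inside the CDS before the main stop (uoORF, the overlapping class), or
at the main stop itself (eCDS). upORF types therefore partition: an ORF
has exactly one type, and eCDS arises exactly when the uTIS position is
a multiple of 3 away from the CDS and no in-frame stop intervenes in the
5'UTR. A uTIS with no in-frame stop before the transcript end (possible
on records without a 3'UTR) is reported as `no_stop` and not counted as
a upORF. Stops spanning the UTR/CDS junction, and the rare stop found
past the CDS in a 3'UTR, are classified with the overlapping class since
the ORF overlaps the CDS either way.

`annotate_variant()` applies the alternate base and re-examines only the
at most three triplet windows (one per frame) overlapping the variant:

* **uTIS created** — a window that is a start codon on the variant
  sequence but carried a different codon on the reference. A created TIS
  is a (position, codon) pair: a variant that converts one start codon
  into another (e.g. AGG→ATG, or ATG→ATA) is reported for the *gained*
  codon; TIS loss is not an annotation class. One consequence of this
  set-difference semantics is that a single SNV can create two distinct
  uTIS in different frames (e.g. an ATG in one window and an ATA in the
  next), giving two records of the same consequence class.
* **uStop created** — a window that becomes TAA/TAG/TGA and was not a
  stop before. A stop only changes the landscape if some upstream
  reference uTIS reaches it: the event is linked to every reference uTIS
  (per `tis_mode`) in frame with it and with no intervening in-frame
  stop on the variant sequence. If the linked uTIS's reference ORF ended
  at a downstream stop, the event is a *shortening*; if it ran to the
  main stop, the new earlier stop defines a *new upORF*. A created stop
  in a frame with no upstream start is silent by default
  (`report_orphan_stops = TRUE` reports it with empty TIS fields).
* **uStop deleted** — a reference stop window overlapping the variant
  that is no longer a stop, and terminated at least one reference upORF.
  Each affected upORF is re-extended on the variant sequence, typically
  elongating a uORF into a longer uORF or into a uoORF ending at the
  next in-frame stop inside the CDS. A change from one stop codon to
  another (TAA→TGA) deletes nothing. The combinatorics are fixed by the
  codon table: of the 9 single-base changes, TAA has 7 deleters (2
  changes keep a stop) while TAG and TGA have 8 each.

The catalog (`build_catalog()`) aggregates per-SNV consequence classes:
an SNV is *multi-consequence* when it triggers at least two distinct
classes (e.g. creating a uAUG in one frame while a second window becomes
a stop that shortens an existing upORF). The partition
`pure uTIS + pure uStop-new + pure uStop-del + multi = annotated` holds
on every input, as does `uORF + uoORF + eCDS = TIS-created upORFs`.

## Kozak context

The translation-efficiency context of a TIS is summarised as the 7-mer
over positions −3..+4 (+1 = first TIS base) and classified by the two
dominant positions only: **strong** = purine at −3 *and* G at +4,
**moderate** = exactly one of the two, **weak** = neither. The same rule
is applied to canonical and near-cognate TIS, and for a variant-created
TIS the context is read from the variant-applied sequence, since the
variant can sit inside its own 7-mer (ENG c.-76C>T turns ACGC**C**GG
into ACGC**T**GG: a strong-context uCUG). A TIS within the first three
transcript bases gets an N-padded 7-mer, is flagged undetermined, and
falls back to weak. Sequence-based strength scores (KSS, PreTIS) are
external predictions; the catalog accepts them as pass-through columns
but does not compute them.

## Design choices

* **Near-cognate set.** All nine single-mismatch codons (CTG, GTG, TTG,
  ACG, AAG, AGG, ATA, ATC, ATT) are eligible under
  `tis_mode = "both"` (the default); `"canonical"` restricts to ATG.
  The same `tis_mode` governs which reference uTIS can anchor stop-gain
  and stop-loss events, so sensitivity to this choice can be probed
  directly.
* **Per-uTIS accounting, no scanning model.** Each uTIS is treated
  independently; no leaky-scanning or re-initiation model is layered on
  top, and no minimum ORF length is imposed. The catalog is a landscape
  of possibilities, not a quantitative translation prediction.
* **Windowed delta, checked against a brute-force oracle.** Correctness
  of the "only three windows can change" shortcut is the central
  property of the package. `brute_force_annotate()` independently
  re-scans *every* window of the reference and variant sequences in all
  frames, diffs the TIS/stop landscapes, and applies the same linkage
  rules with its own coordinate and classification code. The test suite
  asserts record-level equality between the two routes over 100 seeded
  random transcripts (5'UTRs of 20–120 nt, all of their SNVs) plus a
  faster 12-transcript slice in the unit tests — sizes chosen to keep
  the default suite in the low minutes while covering thousands of
  variants per run.
* **Transcript-space VCF.** The saturation VCF uses the transcript as
  its contig, POS as the 1-based offset in 5'UTR + CDS, and carries
  HGVS c. notation in INFO (`HGVSC`), with annotation in `UTRSAT_CSQ`;
  reading validates every REF base against the transcript.

## The synthetic data generator

`random_transcript()` emulates the structural features the annotator
depends on: a random 5'UTR of configurable length, a CDS assembled from
non-stop codons (so CDS validity holds by construction), and optional
planted motifs that are re-validated after insertion. It reproduces a
given seed exactly and leaves the caller's RNG state untouched.

`synthetic_eng_like()` is a deterministic stand-in for the ENG MANE
transcript (303-nt 5'UTR, 1977-nt CDS). It embeds only the documented
landscape: the local reference context around each of the 14
experimentally characterised uTIS-creating variants (reconstructed from
their published variant-applied 7-mers and upORF sizes — the overlapping
reconstructions agree at every shared base and independently imply the
TGA at c.-166 and TAA at c.-34), the shared uoORF stops at c.125 and
c.90, reference uAUGs terminating at the two upstream stops, and a
strong-Kozak main ATG. Filler positions are seeded random sequence
repaired so no stray stop interrupts the engineered frames. What this
does **not** emulate is the full reference sequence: global saturation
counts on the synthetic construct are not comparable to the real
transcript, so tests assert per-variant worked examples on it, and the
full published catalog counts only against a user-supplied
`ENST00000373203.9` cDNA FASTA (placed in `inst/extdata/`; it is not
redistributed with the package).

## Degenerate inputs and numerical corners

Sequences are upper-cased and U→T converted on load; ambiguity codes are
rejected because every annotation is defined on concrete bases. Variants
are accepted only in the 5'UTR; the REF base is always validated against
the transcript. Zero-length catalogs write header-only TSVs and
variant-free VCFs. All outputs are deterministically ordered (position,
then alternate base A<C<G<T, then record order), so repeated runs are
byte-identical.

## Limitations

The annotator is deliberately transcript-centric: one isoform, no
genomic coordinates or liftover, SNVs only (no indels or MNVs). It
predicts which upORFs *can* be created or altered, not whether they are
translated or pathogenic; integrating ribosome profiling evidence,
initiation-efficiency scores or clinical classification is downstream of
the catalog it produces.
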