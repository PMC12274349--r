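# uorfsat

Saturation annotation of upORF-altering variants in transcript 5'UTRs.

Upstream open reading frames (upORFs) start at an upstream translation
initiation site (uTIS) in the 5'UTR of an mRNA — the canonical AUG or a
near-cognate codon one mismatch away — and can repress translation of the
main coding sequence. In *ENG*, the gene whose loss of function causes
Hereditary Hemorrhagic Telangiectasia (HHT), 5'UTR variants creating
overlapping upORFs (uoORFs) that end at the in-CDS stop codon at c.125
reduce Endoglin levels and are clinically relevant. `uorfsat` makes this
class of variant interpretable *before* a variant is ever observed, by
exhaustive in-silico saturation: for an `L`-nt 5'UTR it enumerates all
`3 × L` possible SNVs and annotates each one as

* **uTIS-creating** — a window becomes a start codon (AUG or one of the
  nine near-cognates CUG/GUG/UUG/ACG/AAG/AGG/AUA/AUC/AUU); the new ORF is
  typed as fully upstream (uORF), CDS-overlapping (uoORF), or elongated
  CDS (eCDS, in frame with the main ORF);
* **uStop-creating** — a window becomes TAA/TAG/TGA in frame with an
  upstream reference uTIS, shortening its upORF or defining a new one;
* **uStop-deleting** — an existing upORF's stop codon is destroyed and
  the ORF elongates to the next in-frame stop.

Every record carries the uTIS, the stop position (first-base convention),
the ORF type and length (stop codon included; in HGVS c. coordinates with
no position zero), and the Kozak context 7-mer classified strong /
moderate / weak from the −3 purine and +4 guanine rule. The windowed
annotator is property-tested against an independent brute-force oracle
that re-scans the full sequence for every variant.

## Worked example

The flagship worked example is ENG c.-76C>T, a variant found in HHT
patients. On the bundled synthetic ENG-like transcript (which embeds the
documented local sequence context of that site):

```r
library(uorfsat)
t <- synthetic_eng_like()
t
#> transcript_model 'ENG_synthetic'
#>   5'UTR: 303 nt (c.-303..c.-1)
#>   CDS:   1977 nt (c.1..c.1977, 659 codons incl. stop)

annotate_variant(t, "c.-76C>T")[, c("consequence", "tis_codon", "tis_c_start",
                                    "stop_c_start", "orf_type", "orf_len_nt",
                                    "kozak_7mer", "kozak_class")]
#>    consequence tis_codon tis_c_start stop_c_start orf_type orf_len_nt kozak_7mer kozak_class
#> 1 uTIS_created       CTG         -77          125    uoORF        204    ACGCTGG      strong
```

The variant creates a uCUG at c.-77 in frame with the stop codon whose
first base is c.125, i.e. a 204-nt uoORF (`c_distance(-77, 127) = 204`),
in a strong Kozak context — the signature shared by the known pathogenic
uAUG-creating variants at this locus. A whole-5'UTR catalog:

```r
cat9 <- build_catalog(t)           # 909 SNVs on a 303-nt 5'UTR
summary(cat9)                      # consequence classes, ORF types,
                                   # stop-position landscape
write_catalog(cat9, t, "eng_sat")  # eng_sat.tsv + eng_sat.vcf (UTRSAT_CSQ)
```

A thin command-line front end is bundled at `inst/scripts/utrsat.R`
(`saturate`, `annotate` — including `--vcf-in` for observed variants —
and `selftest`).

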