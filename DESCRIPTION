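Package: uorfsat
Title: Saturation Annotation of upORF-Altering Variants in 5'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico saturation mutagenesis of transcript 5' untranslated
    regions and annotation of the resulting single-nucleotide variants for
    their effect on upstream open reading frames (upORFs). Variants are
    classified as creating canonical (AUG) or near-cognate upstream
    translation initiation sites, creating new upstream stop codons, or
    deleting existing ones; every event is resolved to an upORF with type
    (fully upstream uORF, CDS-overlapping uoORF, or elongated CDS),
    coordinates in HGVS c. space, length, and Kozak context strength.
    Includes a transcript-space VCF/TSV catalog writer, a seeded synthetic
    transcript generator, and an independent brute-force oracle used to
    property-test the windowed annotator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
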