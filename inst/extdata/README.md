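# extdata

Place the real ENG MANE transcript cDNA here to enable the full-catalog
reproduction test:

    ENST00000373203.9.fa   — cDNA FASTA (GRCh38; 303-nt 5'UTR, 1977-nt CDS)

It is not redistributed with the package; fetch it from Ensembl, e.g.
https://rest.ensembl.org/sequence/id/ENST00000373203?type=cdna

All other fixtures are generated programmatically at test time
(`random_transcript()`, `synthetic_eng_like()`).
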