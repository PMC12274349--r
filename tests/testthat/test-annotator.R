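test_that("a created TIS always overlaps the variant and is gained, not moved", {
  t <- toy_inert()
  # no window of the all-C UTR can gain a TIS or stop with one substitution
  for (i in seq_len(nrow(enumerate_snvs(t))))
    expect_identical(nrow(annotate_variant(t, enumerate_snvs(t)[i, ])), 0L)

  t2 <- transcript_model(utr5 = "CCACGCC", cds = "ATGAAATGA")
  cat2 <- build_catalog(t2)
  created <- cat2$records[cat2$records$consequence == "uTIS_created", ]
  # every created TIS triplet contains its variant position
  expect_true(all(created$c_pos >= created$tis_c_start &
                    created$c_pos <= created$tis_c_start + 2L))
})

test_that("variants inside an existing TIS report only the gained codon", {
  # uATG at c.-5; c.-3G>A destroys it while gaining the near-cognate ATA
  t <- transcript_model(utr5 = "CCATGCC", cds = "ATGAAATGA")
  r <- annotate_variant(t, "c.-3G>A", tis_mode = "both")
  gains <- r[r$consequence == "uTIS_created", ]
  expect_true("ATA" %in% gains$tis_codon)
  expect_true(all(gains$tis_codon != "ATG"))
  expect_true(all(gains$tis_codon %in% tis_codons("both")))
})

test_that("stop creation links to an upstream in-frame reference uTIS", {
  # uATG at c.-12 running into the CDS; c.-6C>A creates TAA in its frame
  t <- transcript_model(utr5 = "ATGAAACCCGCC", cds = "ATGAAACCCTGA")
  expect_identical(reference_uporfs(t, "canonical")$orf_type, "eCDS")
  r <- annotate_variant(t, "c.-6C>T", tis_mode = "canonical")
  # TAA needs two changes; c.-6C>T gives CCC->TCC: no stop, no record
  expect_identical(nrow(r), 0L)

  t2 <- transcript_model(utr5 = "ATGAAACCCTCA", cds = "ATGAAACCCTGA")
  r2 <- annotate_variant(t2, "c.-2C>A", tis_mode = "canonical")
  stopgain <- r2[r2$consequence == "uStop_created", ]
  expect_identical(nrow(stopgain), 1L)
  expect_identical(stopgain$tis_c_start, -12L)
  expect_identical(stopgain$event_stop_c_start, -3L)
  # the reference ORF ran to the main stop: the new stop defines a new upORF
  expect_identical(stopgain$stop_change, "new_uporf")
  expect_identical(stopgain$orf_type, "uORF")
  expect_identical(stopgain$orf_len_nt, 12L)

  # same stop gain with no upstream start in that frame: silent by default
  t3 <- transcript_model(utr5 = "CCCCCCCCCTCA", cds = "ATGAAACCCTGA")
  r3 <- annotate_variant(t3, "c.-2C>A", tis_mode = "canonical")
  expect_identical(nrow(r3), 0L)
  r3o <- annotate_variant(t3, "c.-2C>A", tis_mode = "canonical",
                          report_orphan_stops = TRUE)
  expect_identical(r3o$consequence, "uStop_created")
  expect_true(is.na(r3o$tis_c_start))
})

test_that("stop deletion elongates the ORF; stop-to-stop changes never delete", {
  t <- toy_uorf("TAA")
  ref <- reference_uporfs(t, "canonical")
  expect_identical(ref$stop_c_start, -5L)

  # TAA -> TAG and TAA -> TGA keep a stop: not deletions
  expect_identical(nrow(resolve_stop_deletion(t, "c.-3A>G", ref[1, ])), 0L)
  expect_identical(nrow(resolve_stop_deletion(t, "c.-4A>G", ref[1, ])), 0L)

  # TAA -> TAC deletes it; the uORF elongates to the next in-frame stop
  del <- resolve_stop_deletion(t, "c.-3A>C", ref[1, ])
  expect_identical(nrow(del), 1L)
  expect_identical(del$consequence, "uStop_deleted")
  expect_identical(del$ref_stop_c_start, -5L)
  expect_true(is.na(del$stop_c_start) || del$stop_c_start != -5L)
  expect_gt(del$orf_len_nt, ref$orf_len_nt[1])
})

test_that("per-stop deleter counts follow the codon combinatorics", {
  expect_identical(count_stop_deleters("TAA"), 7L)
  expect_identical(count_stop_deleters("TAG"), 8L)
  expect_identical(count_stop_deleters("TGA"), 8L)
})

test_that("multi-consequence variants are annotated once per event", {
  t <- synthetic_eng_like()
  # uATG creation plus shortening of the c.-34-terminated upORF
  r <- annotate_variant(t, "c.-37G>T")
  expect_setequal(unique(r$consequence), c("uTIS_created", "uStop_created"))
  expect_identical(r$event_stop_c_start[r$consequence == "uStop_created"][1],
                   -37L)
  expect_true(all(r$stop_change[r$consequence == "uStop_created"] ==
                    "shortening"))

  # one SNV can create two different uTIS (single consequence class)
  r2 <- annotate_variant(t, "c.-287C>A")
  expect_identical(unique(r2$consequence), "uTIS_created")
  expect_setequal(r2$tis_codon, c("ATG", "ATA"))
  expect_setequal(r2$orf_type, c("uoORF", "uORF"))
})

test_that("catalog partition identities hold and output round-trips", {
  for (t in list(random_transcript(11, 40, 12), toy_uorf("TGA"),
                 toy_inert())) {
    cat9 <- build_catalog(t)
    s <- cat9$summary
    expect_identical(s$n_pure_uTIS + s$n_pure_uStop_new + s$n_pure_uStop_del +
                       s$n_multi, s$n_annotated)
    expect_identical(s$n_uORF + s$n_uoORF + s$n_eCDS, s$n_uTIS_uporfs)
    expect_lte(s$n_annotated, s$n_snvs)
    expect_identical(s$n_uporfs, sum(!is.na(cat9$records$orf_len_nt)))
  }

  t <- toy_uorf("TGA")
  cat9 <- build_catalog(t)
  d <- withr::local_tempdir()
  paths <- write_catalog(cat9, t, file.path(d, "toy"))
  back <- read_catalog_tsv(paths[["tsv"]])
  expect_identical(nrow(back), nrow(cat9$records))
  ord <- order(cat9$records$c_pos, cat9$records$alt)
  expect_identical(back$hgvs_c, cat9$records$hgvs_c[ord])
  expect_identical(back$orf_len_nt, cat9$records$orf_len_nt[ord])
  vcf_snvs <- read_vcf(paths[["vcf"]], t)
  expect_identical(nrow(vcf_snvs), length(unique(cat9$records$hgvs_c)))

  # an empty catalog writes a header-only TSV
  cat0 <- build_catalog(toy_inert())
  paths0 <- write_catalog(cat0, toy_inert(), file.path(d, "empty"))
  expect_identical(nrow(read_catalog_tsv(paths0[["tsv"]])), 0L)
})

test_that("variants outside the 5'UTR are rejected", {
  t <- toy_uorf()
  expect_error(annotate_variant(t, "c.2T>A"), "5'UTR")
})
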