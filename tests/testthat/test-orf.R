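test_that("scan_tis finds canonical and near-cognate windows 5' to 3'", {
  t <- toy_acg_atg()
  can <- scan_tis(t, tis_mode = "canonical")
  expect_identical(can$c_start, -4L)
  expect_identical(can$codon, "ATG")

  both <- scan_tis(t, tis_mode = "both")
  expect_identical(both$c_start, c(-7L, -4L))
  expect_identical(both$codon, c("ACG", "ATG"))
  expect_identical(both$canonical, c(FALSE, TRUE))

  none <- transcript_model(utr5 = "CCCCCC", cds = "ATGAAATGA")
  expect_identical(nrow(scan_tis(none, tis_mode = "both")), 0L)
})

test_that("extend_orf walks to the first in-frame stop and classifies", {
  t <- transcript_model(utr5 = "ATGTAAC", cds = "ATGAAATGA")
  orf <- extend_orf(t, -7L)
  expect_identical(orf$orf_type, "uORF")
  expect_identical(orf$stop_c_start, -4L)
  expect_identical(orf$orf_len_nt, 6L)

  # a TIS in frame with the CDS runs through it to the main stop (eCDS)
  t2 <- transcript_model(utr5 = "ATGCCC", cds = "ATGAAATGA")
  orf2 <- extend_orf(t2, -6L)
  expect_identical(orf2$orf_type, "eCDS")
  expect_true(orf2$ends_at_main_stop)
  expect_identical(orf2$orf_len_nt, 6L + 9L)

  # out-of-frame TIS with no stop before the transcript end
  t3 <- transcript_model(utr5 = "ATGCCCC", cds = "ATGAAATGA")
  orf3 <- extend_orf(t3, -7L)
  expect_identical(orf3$orf_type, "no_stop")
  expect_true(is.na(orf3$orf_len_nt))

  expect_error(extend_orf(t, 2L), "within the 5'UTR")
})

test_that("upORF lengths are multiples of 3 and types partition correctly", {
  for (s in 1:8) {
    t <- random_transcript(seed = s, utr5_len = 15 + 7 * s, cds_codons = 6 + s)
    orfs <- reference_uporfs(t, tis_mode = "both")
    real <- orfs[orfs$orf_type != "no_stop", ]
    if (nrow(real) == 0L) next
    expect_true(all(real$orf_len_nt %% 3L == 0L))
    expect_true(all(real$orf_type %in% c("uORF", "uoORF", "eCDS")))
    # eCDS exactly when the TIS is in CDS frame and the ORF ends at the main stop
    expect_identical(real$orf_type == "eCDS",
                     abs(real$tis_c_start) %% 3L == 0L & real$ends_at_main_stop)
    # in-frame TIS always reaches the main stop unless a frame-aligned stop
    # precedes the CDS; either way it never yields a uoORF
    expect_false(any(real$orf_type == "uoORF" &
                       abs(real$tis_c_start) %% 3L == 0L))
  }
})

test_that("reference_uporfs deduplicates by TIS and stop", {
  # two planted uATGs in the same frame share one stop: two distinct upORFs
  t <- transcript_model(utr5 = "ATGCCCATGCCCTAACC", cds = "ATGAAATGA")
  orfs <- reference_uporfs(t, tis_mode = "canonical")
  expect_identical(nrow(orfs), 2L)
  expect_identical(unique(orfs$stop_c_start), -5L)
  expect_identical(orfs$tis_c_start, c(-17L, -11L))

  none <- transcript_model(utr5 = "CCCCCC", cds = "ATGAAATGA")
  expect_identical(nrow(reference_uporfs(none)), 0L)
})
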