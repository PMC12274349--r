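test_that("coding coordinates map to and from sequence offsets", {
  t <- transcript_model(utr5 = paste0(strrep("C", 302L), "A"),
                        cds = "ATGAAATGA", id = "x")
  expect_identical(c_to_index(t, -303L), 0L)
  expect_identical(c_to_index(t, 1L), 303L)
  expect_identical(c_to_index(t, -1L), 302L)
  expect_error(c_to_index(t, 0L), "no position 0")
  expect_error(c_to_index(t, -304L), "out of range")
  expect_error(c_to_index(t, 400L), "out of range")

  # bijection over the full valid range
  idx <- 0:(nchar(t$seq) - 1L)
  expect_identical(c_to_index(t, index_to_c(t, idx)), idx)
})

test_that("c_distance counts nucleotides inclusively across the missing zero", {
  expect_identical(c_distance(-77L, 127L), 204L)
  expect_identical(c_distance(-143L, 127L), 270L)
  expect_identical(c_distance(5L, 5L), 1L)
  expect_error(c_distance(10L, 5L), "p <= q")
  expect_error(c_distance(-3L, 0L), "no position 0")

  # distance equals the length of the extracted subsequence
  t <- random_transcript(seed = 7, utr5_len = 25, cds_codons = 8)
  pos <- index_to_c(t, 0:(nchar(t$seq) - 1L))
  for (k in 1:25) {
    pq <- sort(sample(pos, 2))
    sub <- substr(t$seq, c_to_index(t, pq[1]) + 1L, c_to_index(t, pq[2]) + 1L)
    expect_identical(c_distance(pq[1], pq[2]), nchar(sub))
  }
})

test_that("transcript invariants are enforced with informative errors", {
  expect_error(transcript_model("ACGT", "ATGAAATG"), "multiple of 3")
  expect_error(transcript_model("ACGT", "ATGTAAAAATGA"), "internal in-frame stop")
  expect_error(transcript_model("ACGT", "CTGAAATGA"), "begin with ATG")
  expect_error(transcript_model("ACGT", "ATGAAAAAA"), "end with a stop")
  expect_error(transcript_model("ACNT", "ATGAAATGA"), "non-ACGT")
  expect_error(transcript_model("", "ATGAAATGA"), "at least one base")

  # RNA alphabet and case are normalised
  t <- transcript_model("acgu", "augaaauga")
  expect_identical(t$utr5, "ACGT")
  expect_identical(t$cds, "ATGAAATGA")
})

test_that("load_transcript reads FASTA + sidecar config and GenBank", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "tx.fa")
  writeLines(c(">tx1 demo", "ACGTTCATGAAATGA"), fa)

  yml <- file.path(d, "tx.yaml")
  writeLines("utr5_len: 6", yml)
  t <- load_transcript(fa, yml)
  expect_identical(t$utr5, "ACGTTC")
  expect_identical(t$cds, "ATGAAATGA")
  expect_identical(t$id, "tx1")

  js <- file.path(d, "tx.json")
  writeLines('{"cds_start": 7, "cds_end": 15}', js)
  t2 <- load_transcript(fa, js)
  expect_identical(t2$cds, t$cds)

  # explicit cds_len leaves a 3'UTR
  writeLines(c(">tx2", "ACGTTCATGAAATGACCC"), fa)
  t3 <- load_transcript(fa, config = list(utr5_len = 6, cds_len = 9))
  expect_identical(t3$utr3, "CCC")

  # invariant violations surface the rule
  writeLines(c(">bad", "ACGTTCATGTAAAAATGA"), fa)
  expect_error(load_transcript(fa, config = list(utr5_len = 6)),
               "internal in-frame stop")
  writeLines(c(">bad2", "ACGTTCATGAAATG"), fa)
  expect_error(load_transcript(fa, config = list(utr5_len = 6)),
               "multiple of 3")

  gb <- file.path(d, "tx.gb")
  writeLines(c(
    "LOCUS       demo_tx      15 bp    mRNA    linear   01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             7..15",
    "ORIGIN",
    "        1 acgttcatga aatga",
    "//"), gb)
  t4 <- load_transcript(gb)
  expect_identical(t4$utr5, "ACGTTC")
  expect_identical(t4$cds, "ATGAAATGA")
  expect_identical(t4$id, "demo_tx")
})
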