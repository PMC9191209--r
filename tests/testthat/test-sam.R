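# SAM ingestion fixtures are handcrafted in code (helper-fixtures.R)

test_that("a minimal proper pair parses to two perfect-eligible records", {
  dir <- withr::local_tempdir()
  seq20 <- strrep("ACGTT", 4)
  p <- make_sam(file.path(dir, "a.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "20M", seq = seq20, nm = 0),
    list(qname = "p1", flag = 147, rname = "refA", pos = 61,
         cigar = "20M", seq = seq20, nm = 0)))
  rec <- read_sam_records(p, "A")
  expect_equal(nrow(rec), 2L)
  expect_equal(sort(rec$mate), c(1L, 2L))
  expect_true(all(rec$perfect))
  expect_true(all(rec$properly_paired))
  expect_equal(rec$pos[rec$mate == 1], 10L)  # converted to 0-based
  expect_equal(rec$score, c(20L, 20L))       # no AS: aligned - NM
})

test_that("secondary alignments are dropped, clipped records kept but not perfect", {
  dir <- withr::local_tempdir()
  seq20 <- strrep("ACGTT", 4)
  p <- make_sam(file.path(dir, "b.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "20M", seq = seq20, nm = 0),
    list(qname = "p1", flag = 99 + 256, rname = "refA", pos = 211,
         cigar = "20M", seq = seq20, nm = 0),            # secondary
    list(qname = "p1", flag = 147, rname = "refA", pos = 61,
         cigar = "19M1S", seq = seq20, nm = 0)))          # 1 bp clip
  rec <- read_sam_records(p, "A")
  expect_equal(nrow(rec), 2L)                             # secondary gone
  clipped <- rec[rec$mate == 2, ]
  expect_true(clipped$mapped)
  expect_false(clipped$full_length)
  expect_false(clipped$perfect)
  expect_equal(clipped$aligned_bases, 19L)
})

test_that("a missing NM tag is fatal unless the CIGAR is in extended form", {
  dir <- withr::local_tempdir()
  seq20 <- strrep("ACGTT", 4)
  p1 <- make_sam(file.path(dir, "c.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "20M", seq = seq20),
    list(qname = "p1", flag = 147, rname = "refA", pos = 61,
         cigar = "20M", seq = seq20)))
  expect_error(read_sam_records(p1, "A"), "NM")

  p2 <- make_sam(file.path(dir, "d.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "18=1X1=", seq = seq20),
    list(qname = "p1", flag = 147, rname = "refA", pos = 61,
         cigar = "20=", seq = seq20)))
  rec <- read_sam_records(p2, "A")
  expect_equal(sort(rec$edit_distance), c(0L, 1L))
  expect_true(any(rec$perfect))   # the 20= mate
  expect_false(all(rec$perfect))  # the 1X mate
})

test_that("per-reference SAM files summarise to competitive pair evidence", {
  dir <- withr::local_tempdir()
  seq20 <- strrep("ACGTT", 4)
  pa <- make_sam(file.path(dir, "A.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "20M", seq = seq20, nm = 0, as = 20),
    list(qname = "p1", flag = 147, rname = "refA", pos = 61,
         cigar = "20M", seq = seq20, nm = 0, as = 20),
    list(qname = "orphan", flag = 73, rname = "refA", pos = 101,
         cigar = "20M", seq = seq20, nm = 0, as = 20)))
  pb <- make_sam(file.path(dir, "B.sam"), "refB", 500, list(
    list(qname = "p1", flag = 99, rname = "refB", pos = 11,
         cigar = "20M", seq = seq20, nm = 1, as = 19),
    list(qname = "p1", flag = 147, rname = "refB", pos = 61,
         cigar = "20M", seq = seq20, nm = 0, as = 20)))
  pe <- pair_alignments_from_sam(c(A = pa, B = pb))
  asn <- classify_pairs(merge_and_filter(pe))
  expect_equal(asn$status[asn$pair_id == "p1"], "unique_perfect")
  expect_equal(asn$refs[asn$pair_id == "p1"][[1]], "A")
  # A outranks B on summed AS (40 vs 39)
  expect_equal(pe$score[pe$pair_id == "p1" & pe$ref_id == "A"], 40L)
  # the orphan mate cannot form a proper pair
  expect_equal(asn$reason[asn$pair_id == "orphan"], "not-properly-paired")
})

test_that("duplicate mate indices for one read name are fatal", {
  dir <- withr::local_tempdir()
  seq20 <- strrep("ACGTT", 4)
  p <- make_sam(file.path(dir, "dup.sam"), "refA", 500, list(
    list(qname = "p1", flag = 99, rname = "refA", pos = 11,
         cigar = "20M", seq = seq20, nm = 0),
    list(qname = "p1", flag = 99, rname = "refA", pos = 31,
         cigar = "20M", seq = seq20, nm = 0)))
  expect_error(pair_alignments_from_sam(c(A = p)), "mate")
})
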