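test_that("genome generation and mutation are deterministic under a seed", {
  g1 <- generate_genome(100, seed = 5)
  g2 <- generate_genome(100, seed = 5)
  expect_identical(g1$sequence, g2$sequence)
  g3 <- generate_genome(100, seed = 6)
  expect_false(identical(g1$sequence, g3$sequence))
  expect_error(generate_genome(0), "positive")

  m1 <- mutate_genome(g1, 0.5, seed = 9)
  m2 <- mutate_genome(g1, 0.5, seed = 9)
  expect_identical(m1$sequence, m2$sequence)
})

test_that("mutation substitutes exactly the requested fraction of sites", {
  g <- generate_genome(1000, seed = 7)
  m0 <- mutate_genome(g, 0, seed = 8)
  expect_identical(m0$sequence, g$sequence)

  m <- mutate_genome(g, 0.05, seed = 8)
  expect_equal(pairwise_identity(g, m), 0.95)
  expect_equal(attr(m, "realized_identity"), 0.95)
  expect_equal(m$length_bp, 1000L)
})

test_that("pairwise identity counts matching positions and rejects unequal lengths", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("ACGT", "ACGTA"), "length")
})

test_that("mixtures respect proportions, determinism and absence", {
  refs <- withr::with_seed(41, reference_set(
    c(A = random_dna(3000), B = random_dna(3000))))
  s1 <- simulate_mixture(refs, c(0.5, 0.5), n_pairs = 10000,
                         read_length = 100, seed = 12)
  s2 <- simulate_mixture(refs, c(0.5, 0.5), n_pairs = 10000,
                         read_length = 100, seed = 12)
  expect_identical(s1$reads, s2$reads)
  expect_equal(sum(s1$truth$n_pairs), 10000L)
  # multinomial draw around 5000/5000 (5 sd)
  expect_lt(abs(s1$truth$n_pairs[1] - 5000), 5 * sqrt(10000 * 0.25))
  expect_equal(sum(s1$truth$true_ra), 1)

  s3 <- simulate_mixture(refs, c(1, 0), n_pairs = 500,
                         read_length = 100, seed = 13)
  expect_true(all(s3$reads$source == "A"))
  expect_equal(s3$truth$n_pairs, c(500L, 0L))

  expect_error(simulate_mixture(refs, c(0.7, 0.7), n_pairs = 10),
               "sum to 1")
  expect_error(simulate_mixture(refs, c(0.5, 0.5, 0), n_pairs = 10),
               "one entry per reference")
})

test_that("error-free pairs always align perfectly back to their source genome", {
  refs <- withr::with_seed(42, {
    a <- generate_genome(4000, ref_id = "A")
    b <- mutate_genome(a, 0.05, ref_id = "B")
    validate_reference_set(dplyr::bind_rows(a, b))
  })
  sim <- simulate_mixture(refs, c(0.6, 0.4), n_pairs = 800,
                          read_length = 100, error_rate = 0, seed = 14)
  asn <- classify_pairs(merge_and_filter(
    align_pairs(refs, sim$reads$mate1, sim$reads$mate2,
                pair_id = sim$reads$pair_id)))
  expect_equal(sum(asn$status == "discarded"), 0L)
  # and every pair's matched set contains its true source
  src <- setNames(sim$reads$source, sim$reads$pair_id)
  hit <- purrr::map2_lgl(asn$refs, src[asn$pair_id], ~ .y %in% .x)
  expect_true(all(hit))
})

test_that("tie status of each error-free pair matches the diff-site positions", {
  refs <- withr::with_seed(43, {
    a <- generate_genome(4000, ref_id = "A")
    b <- mutate_genome(a, 0.02, ref_id = "B")
    validate_reference_set(dplyr::bind_rows(a, b))
  })
  diff_sites <- which(strsplit(refs$sequence[1], "")[[1]] !=
                        strsplit(refs$sequence[2], "")[[1]])
  sim <- simulate_mixture(refs, c(1, 0), n_pairs = 400,
                          read_length = 100, error_rate = 0, seed = 15)
  asn <- classify_pairs(merge_and_filter(
    align_pairs(refs, sim$reads$mate1, sim$reads$mate2,
                pair_id = sim$reads$pair_id)))
  # oracle: a pair ties iff neither mate window covers a diff site
  rd <- sim$reads
  L <- 100
  covers <- function(start0, insert) {
    w1 <- (start0 + 1):(start0 + L)
    s2 <- start0 + L + insert
    w2 <- (s2 + 1):(s2 + L)
    any(diff_sites %in% c(w1, w2))
  }
  want_unique <- purrr::map2_lgl(rd$start, rd$insert, covers)
  got <- setNames(asn$status, asn$pair_id)[rd$pair_id]
  expect_equal(unname(got == "unique_perfect"), want_unique)
  expect_equal(unname(got == "tied_perfect"), !want_unique)
})

test_that("FASTQ round-trip preserves reads byte for byte", {
  refs <- withr::with_seed(44, reference_set(c(A = random_dna(2000))))
  sim <- simulate_mixture(refs, 1, n_pairs = 200, read_length = 80,
                          seed = 16)
  dir <- withr::local_tempdir()
  paths <- write_mixture(sim, dir, prefix = "t", gzip = TRUE)
  back <- read_fastq_pairs(paths$fastq1, paths$fastq2)
  expect_equal(back$mate1, sim$reads$mate1)
  expect_equal(back$mate2, sim$reads$mate2)
  expect_equal(back$pair_id, sim$reads$pair_id)
  truth <- readr::read_tsv(paths$truth, show_col_types = FALSE)
  expect_equal(truth$true_relative_abundance, 1)
})
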