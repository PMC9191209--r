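# internal aligner wrappers around the compiled search
#
# The compiled core enumerates every full-length ungapped placement of a
# read (both strands) whose Hamming distance to the genome is at most
# `max_mismatches`, then pairs placements into proper pairs
# (forward-reverse, forward mate upstream, inner insert within bounds).
# Coordinates are 0-based half-open internally.

KMER_K <- 16L

as_genome <- function(genome) {
  if (is.data.frame(genome)) {
    genome <- validate_reference_set(genome)
    if (nrow(genome) != 1L)
      stopf("expected a single genome, got %d", nrow(genome))
    genome$sequence
  } else if (is_string(genome)) toupper(genome) else
    stopf("`genome` must be a one-row reference set or a string")
}

#' Enumerate all ungapped placements of reads on one genome
#'
#' Exhaustively reports every full-length, ungapped placement (forward and
#' reverse strand) of each read with Hamming distance at most
#' `max_mismatches`.  `N` in either read or genome counts as a mismatch.
#'
#' @param genome A one-row `reference_set` or a sequence string.
#' @param reads Character vector of read sequences.
#' @param max_mismatches Maximum Hamming distance per read (default 4).
#' @return Tibble with columns `read` (index into `reads`), `pos` (0-based
#'   leftmost coordinate), `strand` (`+`/`-`) and `mismatches`.
#' @export
enumerate_placements <- function(genome, reads, max_mismatches = 4L) {
  if (max_mismatches < 0L) stopf("`max_mismatches` must be >= 0")
  seq <- as_genome(genome)
  as_tibble(enumerate_placements_cpp(seq, toupper(reads),
                                     as.integer(max_mismatches), KMER_K))
}

#' Align one read pair against one genome
#'
#' Self-contained paired-end alignment of a single pair: all co-best
#' proper-pair placements are found and the pair-level evidence (score,
#' perfectness, primary placement) reported, alongside the per-mate
#' placement lists.  The primary placement is the co-best proper pair with
#' the smallest fragment coordinate, mate1-forward orientation first.
#'
#' @param mate1,mate2 Read sequences (single strings).
#' @param genome A one-row `reference_set` or sequence string.
#' @param max_mismatches Maximum per-mate Hamming distance.
#' @param min_insert,max_insert Inner insert (gap between the two mates)
#'   bounds defining a proper pair, in bases.
#' @return A list with `placements` (per-mate tibble as
#'   [enumerate_placements()], plus `mate`) and `pair` (one-row tibble of
#'   pair-level evidence as returned by [align_pairs()]).
#' @export
align_read_pair <- function(mate1, mate2, genome, max_mismatches = 4L,
                            min_insert = 0L, max_insert = 1000L) {
  seq <- as_genome(genome)
  pl1 <- enumerate_placements(seq, mate1, max_mismatches) %>%
    mutate(mate = 1L, .before = 1)
  pl2 <- enumerate_placements(seq, mate2, max_mismatches) %>%
    mutate(mate = 2L, .before = 1)
  placements <- bind_rows(pl1, pl2) %>% select(-"read")
  pair <- as_tibble(align_pairs_cpp(seq, toupper(mate1), toupper(mate2),
                                    as.integer(max_mismatches),
                                    as.integer(min_insert),
                                    as.integer(max_insert), KMER_K))
  list(placements = placements, pair = pair)
}

#' Competitively align read pairs against every reference
#'
#' Runs the built-in exact ungapped paired-end aligner for each genome of
#' the reference set and returns per-(pair, reference) alignment evidence,
#' ready for [merge_and_filter()].  Only references where at least one
#' mate maps at all are reported; the full set of pair identifiers travels
#' as an attribute so downstream filtering can account for fully unmapped
#' pairs.
#'
#' @param refs A `reference_set`.
#' @param mate1,mate2 Character vectors of read sequences, one pair per
#'   element.
#' @param pair_id Optional pair identifiers; defaults to `pair000001`, ...
#' @inheritParams align_read_pair
#' @return Tibble with columns `pair_id`, `ref_id`, `any_mapped`,
#'   `properly_paired`, `score`, `perfect`, `mapped_bases`, `mm1`, `mm2`,
#'   `pos1`, `pos2`, `strand1`, `n_best`; attribute `pair_ids` lists every
#'   input pair.
#' @export
align_pairs <- function(refs, mate1, mate2, pair_id = NULL,
                        max_mismatches = 4L, min_insert = 0L,
                        max_insert = 1000L) {
  refs <- validate_reference_set(refs)
  if (length(mate1) != length(mate2))
    stopf("mate1 and mate2 must have equal length")
  if (is.null(pair_id))
    pair_id <- sprintf("pair%06d", seq_along(mate1))
  if (anyDuplicated(pair_id)) stopf("duplicate pair_id")
  m1 <- toupper(mate1); m2 <- toupper(mate2)
  out <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    hits <- as_tibble(align_pairs_cpp(refs$sequence[i], m1, m2,
                                      as.integer(max_mismatches),
                                      as.integer(min_insert),
                                      as.integer(max_insert), KMER_K))
    keep <- hits$any_mapped
    if (!any(keep)) next
    out[[i]] <- tibble(pair_id = pair_id[keep], ref_id = refs$ref_id[i]) %>%
      bind_cols(hits[keep, ])
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble(pair_id = character(), ref_id = character(),
                  any_mapped = logical(), properly_paired = logical(),
                  score = integer(), perfect = logical(),
                  mapped_bases = integer(), mm1 = integer(), mm2 = integer(),
                  pos1 = integer(), pos2 = integer(), strand1 = character(),
                  n_best = integer())
  attr(res, "pair_ids") <- pair_id
  res
}

#' Reverse complement of nucleotide sequences
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements (non-ACGT letters map
#'   to `N`).
#' @export
reverse_complement <- function(x) revcomp_cpp(x)
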