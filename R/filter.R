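# merge-and-filter of competitive alignments, and pair classification
#
# After every reference has been aligned (internally or via ingested
# SAM/BAM), each pair is kept for exactly the set of references achieving
# its best pair-level score among references where it is properly paired;
# pairs proper nowhere are discarded with a reason.  Classification then
# splits kept pairs into unique-perfect / tied-perfect / imperfect.

#' Merge per-reference alignments and keep best-scoring proper pairs
#'
#' For each pair, the pair-level score per reference is the sum of its two
#' primary mate scores where both mates are mapped and properly paired on
#' that reference.  The pair is kept for exactly the references achieving
#' the maximum such score; references where the pair maps but is not
#' properly paired never enter the competition.  Pairs with no properly
#' paired reference are discarded with reason `not-properly-paired` (mapped
#' somewhere) or `unmapped` (mapped nowhere).
#'
#' @param pair_alignments Tibble from [align_pairs()] or
#'   [pair_alignments_from_sam()].
#' @param pair_ids All pair identifiers in the sample (defaults to the
#'   `pair_ids` attribute); pairs absent from `pair_alignments` are
#'   discarded as `unmapped`.
#' @return Tibble with one row per kept (pair, reference) plus one row per
#'   discarded pair: columns `pair_id`, `ref_id` (`NA` when discarded),
#'   `kept`, `reason` (`NA` when kept), `score`, `perfect`,
#'   `mapped_bases`.  Attribute `pair_ids` is preserved.
#' @export
merge_and_filter <- function(pair_alignments,
                             pair_ids = attr(pair_alignments, "pair_ids")) {
  pa <- as_tibble(pair_alignments)
  if (is.null(pair_ids)) pair_ids <- unique(pa$pair_id)

  proper <- pa %>% filter(.data$properly_paired)
  if (nrow(proper) > 0) {
    kept <- proper %>%
      group_by(.data$pair_id) %>%
      filter(.data$score == max(.data$score)) %>%
      ungroup()
  } else {
    kept <- proper
  }
  kept <- kept %>%
    mutate(kept = TRUE, reason = NA_character_) %>%
    select("pair_id", "ref_id", "kept", "reason", "score", "perfect",
           "mapped_bases")

  lost <- setdiff(pair_ids, kept$pair_id)
  mapped_somewhere <- unique(pa$pair_id[pa$any_mapped %||% TRUE])
  discarded <- tibble(
    pair_id = lost,
    ref_id = NA_character_,
    kept = FALSE,
    reason = if_else(lost %in% mapped_somewhere,
                     "not-properly-paired", "unmapped"),
    score = NA_integer_, perfect = NA, mapped_bases = NA_integer_)

  out <- bind_rows(kept, discarded)
  attr(out, "pair_ids") <- pair_ids
  out
}

#' Classify filtered pairs into unique, tied and discarded
#'
#' Kept pairs perfect on exactly one reference become `unique_perfect`;
#' perfect on two or more references, `tied_perfect` (the tied reference
#' set is retained); kept pairs with no perfect alignment anywhere are
#' discarded as `imperfect`.  Upstream discards pass through with their
#' reason.  Only perfect pairs are ever assigned bases downstream.
#'
#' @param filtered Output of [merge_and_filter()].
#' @return Tibble of class `assignment_tbl`, one row per pair: `pair_id`,
#'   `status` (`unique_perfect`/`tied_perfect`/`discarded`), `refs`
#'   (list-column of tied or matched reference ids), `reason`,
#'   `mapped_bases`.
#' @export
classify_pairs <- function(filtered) {
  kept <- filtered %>% filter(.data$kept)
  cls <- kept %>%
    group_by(.data$pair_id) %>%
    summarise(
      refs = list(sort(.data$ref_id[.data$perfect])),
      mapped_bases = if (any(.data$perfect)) max(.data$mapped_bases[.data$perfect])
                     else .data$mapped_bases[1],
      .groups = "drop") %>%
    mutate(
      n_perfect = lengths(.data$refs),
      status = dplyr::case_when(.data$n_perfect == 1L ~ "unique_perfect",
                                .data$n_perfect >= 2L ~ "tied_perfect",
                                TRUE ~ "discarded"),
      reason = if_else(.data$n_perfect == 0L, "imperfect", NA_character_)) %>%
    select("pair_id", "status", "refs", "reason", "mapped_bases")

  disc <- filtered %>%
    filter(!.data$kept) %>%
    mutate(status = "discarded", refs = list(character())) %>%
    select("pair_id", "status", "refs", "reason", "mapped_bases")

  out <- bind_rows(cls, disc)
  class(out) <- unique(c("assignment_tbl", class(out)))
  out
}

#' Tally tie groups from classified pairs
#'
#' Groups tied-perfect pairs by their (sorted) tied reference set and sums
#' their mapped bases; these groups are what the quantifier's tie passes
#' resolve.
#'
#' @param assignments An `assignment_tbl` from [classify_pairs()].
#' @return Tibble with `members` (list of ref_id sets), `key` (collapsed
#'   member string), `mapped_bases`, `n_pairs`, sorted by `key`.
#' @export
tie_groups <- function(assignments) {
  tied <- assignments %>% filter(.data$status == "tied_perfect")
  if (nrow(tied) == 0L)
    return(tibble(key = character(), members = list(),
                  mapped_bases = numeric(), n_pairs = integer()))
  tied %>%
    mutate(key = purrr::map_chr(.data$refs, paste, collapse = "\t")) %>%
    group_by(.data$key) %>%
    summarise(members = .data$refs[1],
              mapped_bases = sum(as.numeric(.data$mapped_bases)),
              n_pairs = dplyr::n(), .groups = "drop") %>%
    arrange(.data$key)
}
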