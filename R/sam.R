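# ingestion of externally produced per-reference alignments (SAM/BAM)
#
# The production route maps each sample against every reference
# individually with an external mapper (e.g. bwa mem) and feeds one
# SAM/BAM per reference here.  Parsing is delegated to Rsamtools; this
# layer keeps primary records only, derives per-mate perfectness from
# CIGAR + NM, and summarises records to per-(pair, reference) evidence of
# the same shape `align_pairs()` produces.

cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  purrr::map2(lens, ops, ~ setNames(as.integer(.x), .y))
}

cigar_sum <- function(ops, which) {
  vapply(ops, function(o) sum(o[names(o) %in% which]), integer(1))
}

#' Parse one reference's SAM/BAM alignments
#'
#' Reads a SAM (plain text) or BAM file of one sample mapped against a
#' single reference genome and returns one record per primary alignment
#' line: secondary (0x100) and supplementary (0x800) records are dropped,
#' unmapped mates are kept and flagged.  Records must carry read names,
#' flags, CIGAR and an `NM` edit-distance tag for mapped records (if `NM`
#' is absent it is recovered from `X`/`I`/`D` CIGAR operations when the
#' CIGAR is in extended form, otherwise parsing stops); `AS` per-mate
#' scores are used when present and otherwise recomputed as aligned bases
#' minus edit distance.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param ref_id Genome identifier the file was mapped against (all
#'   mapped records are attributed to it, whatever their contig name).
#' @return Tibble with one row per primary record: `pair_id`, `mate`,
#'   `ref_id`, `mapped`, `properly_paired`, `pos` (0-based), `cigar`,
#'   `edit_distance`, `score`, `read_length`, `aligned_bases`,
#'   `full_length`, `perfect`.
#' @export
read_sam_records <- function(path, ref_id) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stopf("malformed SAM %s: %s", path,
                                conditionMessage(e)))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "qwidth"),
    tag = c("NM", "AS"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  rec <- tibble(
    pair_id = x$qname,
    flag = flag,
    pos = x$pos - 1L,             # SAM is 1-based; internal is 0-based
    cigar = x$cigar,
    read_length = x$qwidth,
    edit_distance = as.integer(x$tag$NM %||% rep(NA_integer_, length(flag))),
    as_tag = as.integer(x$tag$AS %||% rep(NA_integer_, length(flag))))[primary, ]

  rec <- rec %>%
    mutate(
      mate = dplyr::case_when(bitwAnd(.data$flag, 0x40) > 0 ~ 1L,
                              bitwAnd(.data$flag, 0x80) > 0 ~ 2L,
                              TRUE ~ NA_integer_),
      mapped = bitwAnd(.data$flag, 0x4) == 0,
      properly_paired = bitwAnd(.data$flag, 0x2) > 0)
  if (anyNA(rec$mate))
    stopf("%s: record without a mate flag (single-end input?)", path)

  ops <- cigar_ops(if_else(rec$mapped, rec$cigar, "0M"))
  aligned <- cigar_sum(ops, c("M", "=", "X"))
  # recover NM from extended CIGAR when the tag is missing
  missing_nm <- rec$mapped & is.na(rec$edit_distance)
  if (any(missing_nm)) {
    extended <- vapply(ops[missing_nm],
                       function(o) any(names(o) %in% c("=", "X")),
                       logical(1))
    if (!all(extended))
      stopf("%s: mapped record(s) lack the NM tag and the CIGAR is not in =/X form",
            path)
    rec$edit_distance[missing_nm] <-
      cigar_sum(ops[missing_nm], c("X", "I", "D"))
  }
  clip_free <- vapply(ops, function(o)
    !any(names(o) %in% c("S", "H", "I", "D", "N", "P")), logical(1))

  rec %>%
    mutate(
      ref_id = ref_id,
      aligned_bases = if_else(.data$mapped, aligned, 0L),
      full_length = .data$mapped & clip_free &
        aligned == .data$read_length,
      perfect = .data$full_length & .data$edit_distance == 0L,
      score = if_else(
        .data$mapped,
        if_else(is.na(.data$as_tag),
                .data$aligned_bases - .data$edit_distance,
                .data$as_tag),
        NA_integer_)) %>%
    select("pair_id", "mate", "ref_id", "mapped", "properly_paired",
           "pos", "cigar", "edit_distance", "score", "read_length",
           "aligned_bases", "full_length", "perfect")
}

#' Summarise per-reference SAM/BAM files to pair-level evidence
#'
#' Ingests one alignment file per reference (named by `ref_id`) and builds
#' the per-(pair, reference) table [merge_and_filter()] consumes.  A pair
#' is properly paired on a reference when both mates are present, mapped
#' and carry the mapper's properly-paired flag; its score is the sum of
#' the two mate scores; it is perfect when both mates align full-length
#' with zero edit distance.  A read name appearing with more than two mate
#' indices is an error; an orphan mate leaves the pair improperly paired.
#'
#' @param paths Named character vector, `ref_id -> path`.
#' @inheritParams read_sam_records
#' @return Tibble as [align_pairs()], with attribute `pair_ids`.
#' @export
pair_alignments_from_sam <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stopf("`paths` must be named by ref_id")
  recs <- purrr::imap(paths, function(p, id) read_sam_records(p, id))
  all_ids <- unique(unlist(lapply(recs, function(r) r$pair_id)))
  per_ref <- purrr::map(recs, function(r) {
    bad <- r %>% count(.data$pair_id, .data$mate) %>% filter(n > 1)
    if (nrow(bad) > 0)
      stopf("pair %s has duplicated mate index %d",
            bad$pair_id[1], bad$mate[1])
    wide <- r %>%
      group_by(.data$pair_id) %>%
      summarise(
        ref_id = .data$ref_id[1],
        n_mates = dplyr::n(),
        any_mapped = any(.data$mapped),
        properly_paired = dplyr::n() == 2L && all(.data$mapped) &&
          all(.data$properly_paired),
        score = sum(.data$score),
        perfect = dplyr::n() == 2L && all(.data$perfect),
        mapped_bases = sum(.data$aligned_bases),
        .groups = "drop")
    if (any(wide$n_mates > 2L))
      stopf("pair %s has more than two mates",
            wide$pair_id[wide$n_mates > 2L][1])
    wide %>%
      mutate(score = if_else(.data$properly_paired, .data$score,
                             NA_integer_)) %>%
      filter(.data$any_mapped) %>%
      select("pair_id", "ref_id", "any_mapped", "properly_paired",
             "score", "perfect", "mapped_bases")
  })
  res <- bind_rows(per_ref)
  attr(res, "pair_ids") <- all_ids
  res
}
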