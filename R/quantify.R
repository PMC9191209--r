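# the quantification core: unique-read anchoring, the coverage and
# relative-abundance equations, the zero-unique tie pre-pass, and
# proportional tie resolution.
#
# All base counts (mbp) are fractional: tied pairs are split by ratio
# rather than assigned read-by-read at random, which equals the
# expectation of the stochastic reading and keeps runs reproducible
# without a seed.

#' Fold-coverage of a reference
#'
#' `C = mbp / g`: bases mapped to the reference divided by its genome
#' length.
#'
#' @param mbp Mapped bases (fractional allowed), `>= 0`.
#' @param g Genome length in bases, `> 0`.
#' @return Numeric coverage.
#' @examples
#' compute_coverage(1000, 500)  # 2
#' @export
compute_coverage <- function(mbp, g) {
  if (any(g <= 0)) stopf("genome length must be positive")
  if (any(mbp < 0)) stopf("mbp must be non-negative")
  mbp / g
}

#' Relative abundance from coverages
#'
#' `RA_ref = C_ref / sum_i C_i`.  When every coverage is zero the result
#' is an all-zero vector flagged degenerate (attribute `degenerate`),
#' never `NaN`.
#'
#' @param coverages Named (or plain) numeric vector of coverages, all
#'   `>= 0`.
#' @return Numeric vector of relative abundances summing to 1 (or all
#'   zero, with `attr(, "degenerate") = TRUE`).
#' @export
compute_relative_abundance <- function(coverages) {
  if (any(coverages < 0)) stopf("coverages must be non-negative")
  ra <- ra_from_coverage(coverages)
  names(ra) <- names(coverages)
  attr(ra, "degenerate") <- sum(coverages) == 0
  ra
}

abundance_stage <- function(mbp, refs, stage) {
  cov <- compute_coverage(mbp, refs$length_bp)
  ra <- ra_from_coverage(cov)
  tibble(ref_id = refs$ref_id, mbp = mbp, coverage = cov, ra = ra,
         stage = stage)
}

#' Seed abundances from unique perfect pairs
#'
#' Each reference's mbp is the summed mapped bases of the pairs that align
#' perfectly to it and to no other reference; coverage and relative
#' abundance follow from the two defining equations.  This temporary RA is
#' what the tie passes allocate against.
#'
#' @param assignments An `assignment_tbl` from [classify_pairs()].
#' @param refs The `reference_set`.
#' @return Abundance tibble (`ref_id`, `mbp`, `coverage`, `ra`,
#'   `stage = "after_unique"`).
#' @export
assign_unique <- function(assignments, refs) {
  refs <- validate_reference_set(refs)
  uniq <- assignments %>% filter(.data$status == "unique_perfect")
  bad <- setdiff(unlist(uniq$refs), refs$ref_id)
  if (length(bad) > 0)
    stopf("assignment mentions unknown reference: %s", bad[1])
  mbp <- setNames(numeric(nrow(refs)), refs$ref_id)
  if (nrow(uniq) > 0) {
    sums <- uniq %>%
      mutate(ref_id = purrr::map_chr(.data$refs, 1)) %>%
      group_by(.data$ref_id) %>%
      summarise(mbp = sum(as.numeric(.data$mapped_bases)), .groups = "drop")
    mbp[sums$ref_id] <- sums$mbp
  }
  abundance_stage(unname(mbp), refs, "after_unique")
}

#' Resolve tie groups containing unsupported references
#'
#' Special-cases ties where at least one tied reference has exactly zero
#' unique-stage mbp while at least one other member has positive
#' unique-stage mbp: such a group's bases go only to the supported
#' members, split in proportion to their current relative abundance
#' (wholly to one member if only one is supported).  RA is recomputed once
#' after all such groups are processed, in canonical (sorted member set)
#' order; groups whose members are all supported or all unsupported are
#' returned untouched.
#'
#' @param table Abundance tibble at stage `after_unique`.
#' @param groups Tie groups from [tie_groups()].
#' @param refs The `reference_set`.
#' @return List with `abundance` (stage `after_zero_unique_ties`) and
#'   `unresolved` (remaining tie groups).
#' @export
resolve_zero_unique_ties <- function(table, groups, refs) {
  refs <- validate_reference_set(refs)
  u_mbp <- setNames(table$mbp, table$ref_id)
  ra <- setNames(table$ra, table$ref_id)
  add <- setNames(numeric(nrow(refs)), refs$ref_id)
  resolved <- logical(nrow(groups))
  for (j in seq_len(nrow(groups))) {
    m <- groups$members[[j]]
    supported <- m[u_mbp[m] > 0]
    if (length(supported) == 0L || length(supported) == length(m)) next
    w <- ra[supported]
    add[supported] <- add[supported] +
      groups$mapped_bases[j] * w / sum(w)
    resolved[j] <- TRUE
  }
  ab <- abundance_stage(unname(u_mbp[refs$ref_id] + add[refs$ref_id]),
                        refs, "after_zero_unique_ties")
  list(abundance = ab, unresolved = groups[!resolved, , drop = FALSE])
}

#' Resolve remaining ties proportionally
#'
#' Every remaining tie group's bases are split among its members in the
#' ratio of the members' current relative abundances, renormalised within
#' the group.  Groups whose members all have zero RA even now are split
#' equally and flagged in the report (attribute `flagged_groups`) rather
#' than dropped.  Coverage and RA are recomputed once at the end, giving
#' the final table.
#'
#' @param table Abundance tibble at stage `after_zero_unique_ties`.
#' @param groups Remaining tie groups (the `unresolved` element of
#'   [resolve_zero_unique_ties()]).
#' @param refs The `reference_set`.
#' @return Final abundance tibble (stage `final`), with attribute
#'   `flagged_groups` naming equal-split groups.
#' @export
resolve_ties <- function(table, groups, refs) {
  refs <- validate_reference_set(refs)
  mbp <- setNames(table$mbp, table$ref_id)
  ra <- setNames(table$ra, table$ref_id)
  flagged <- character()
  for (j in seq_len(nrow(groups))) {
    m <- groups$members[[j]]
    w <- ra[m]
    if (sum(w) > 0) {
      mbp[m] <- mbp[m] + groups$mapped_bases[j] * w / sum(w)
    } else {
      mbp[m] <- mbp[m] + groups$mapped_bases[j] / length(m)
      flagged <- c(flagged, paste(m, collapse = ","))
    }
  }
  out <- abundance_stage(unname(mbp[refs$ref_id]), refs, "final")
  attr(out, "flagged_groups") <- flagged
  out
}

#' Quantify a classified sample
#'
#' Orchestrates the two-phase procedure: unique perfect pairs seed
#' per-reference abundances; tie groups with unsupported members are
#' resolved in a pre-pass (bases to the supported members only, RA
#' recomputed once); remaining ties are split proportionally to the
#' current RA; the final coverages and relative abundances follow from
#' `C = mbp/g` and `RA = C / sum(C)`.  Optionally, references below a
#' minimum-RA noise threshold are zeroed and the rest renormalised.
#'
#' @param assignments An `assignment_tbl` from [classify_pairs()].
#' @param refs The `reference_set`.
#' @param min_ra Optional noise threshold in `[0, 1)`; final RA values
#'   below it are set to zero and the remainder renormalised (default 0 =
#'   off).
#' @return An object of class `genome_quant`: list with `abundance` (final
#'   stage tibble), `stages` (all three stages bound together), and
#'   `report` (pair counts by outcome, discard reasons, flagged tie
#'   groups, degenerate flag).  See [tidy.genome_quant()],
#'   [glance.genome_quant()], [autoplot.genome_quant()].
#' @examples
#' refs <- reference_set(c(A = strrep("AC", 50), B = strrep("GT", 50)))
#' asn <- tibble::tibble(
#'   pair_id = paste0("p", 1:8),
#'   status = c(rep("unique_perfect", 3), "unique_perfect",
#'              rep("tied_perfect", 4)),
#'   refs = c(rep(list("A"), 3), list("B"), rep(list(c("A", "B")), 4)),
#'   reason = NA_character_, mapped_bases = 20)
#' quantify(asn, refs)$abundance
#' @export
quantify <- function(assignments, refs, min_ra = 0) {
  refs <- validate_reference_set(refs)
  if (min_ra < 0 || min_ra >= 1) stopf("`min_ra` must be in [0, 1)")

  stage1 <- assign_unique(assignments, refs)
  groups <- tie_groups(assignments)
  pre <- resolve_zero_unique_ties(stage1, groups, refs)
  final <- resolve_ties(pre$abundance, pre$unresolved, refs)

  thresholded <- FALSE
  if (min_ra > 0 && any(final$ra > 0)) {
    keep <- final$ra >= min_ra
    if (!all(keep)) {
      final$mbp[!keep] <- 0
      final <- abundance_stage(final$mbp, refs, "final")
      thresholded <- TRUE
    }
  }

  n_disc <- assignments %>%
    filter(.data$status == "discarded") %>%
    count(.data$reason)
  report <- list(
    n_pairs = nrow(assignments),
    n_unique = sum(assignments$status == "unique_perfect"),
    n_tied = sum(assignments$status == "tied_perfect"),
    n_discarded = sum(assignments$status == "discarded"),
    discard_reasons = setNames(n_disc$n, n_disc$reason),
    n_tie_groups = nrow(groups),
    n_zero_unique_groups_resolved = nrow(groups) - nrow(pre$unresolved),
    flagged_groups = attr(final, "flagged_groups") %||% character(),
    degenerate = sum(final$coverage) == 0,
    min_ra = min_ra,
    thresholded = thresholded)

  structure(
    list(abundance = final,
         stages = bind_rows(stage1, pre$abundance, final),
         report = report,
         refs = refs %>% select("ref_id", "length_bp")),
    class = "genome_quant")
}

#' @export
print.genome_quant <- function(x, ...) {
  r <- x$report
  cat(sprintf("<genome_quant> %d references, %d pairs (%d unique, %d tied, %d discarded)\n",
              nrow(x$abundance), r$n_pairs, r$n_unique, r$n_tied,
              r$n_discarded))
  if (r$degenerate) cat("  [degenerate: no perfect pairs assigned]\n")
  print(x$abundance %>% select(-"stage"))
  invisible(x)
}

#' Tidy a quantification result
#'
#' @param x A `genome_quant`.
#' @param stage Which stage(s) to return (default final only).
#' @param ... Unused.
#' @return Tibble of per-reference `mbp`, `coverage`, `ra`.
#' @method tidy genome_quant
#' @export
tidy.genome_quant <- function(x, stage = "final", ...) {
  x$stages %>% filter(.data$stage %in% !!stage)
}

#' One-row summary of a quantification run
#'
#' @param x A `genome_quant`.
#' @param ... Unused.
#' @return One-row tibble of pair counts and flags.
#' @method glance genome_quant
#' @export
glance.genome_quant <- function(x, ...) {
  r <- x$report
  tibble(n_refs = nrow(x$abundance), n_pairs = r$n_pairs,
         n_unique = r$n_unique, n_tied = r$n_tied,
         n_discarded = r$n_discarded, n_tie_groups = r$n_tie_groups,
         n_flagged_groups = length(r$flagged_groups),
         degenerate = r$degenerate)
}

#' Plot per-reference relative abundances by stage
#'
#' @param object A `genome_quant`.
#' @param ... Unused.
#' @return A ggplot bar chart of RA per reference, one panel per
#'   quantification stage.
#' @method autoplot genome_quant
#' @export
autoplot.genome_quant <- function(object, ...) {
  dat <- object$stages %>%
    mutate(stage = factor(.data$stage,
                          c("after_unique", "after_zero_unique_ties",
                            "final")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ref_id, y = .data$ra)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "reference", y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write the abundance table and run report
#'
#' Writes the final abundance table as TSV (`reference_id`, `mbp`,
#' `coverage`, `relative_abundance`) and the run report as tab-separated
#' `key value` lines.
#'
#' @param x A `genome_quant`.
#' @param abundance_path,report_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_quant <- function(x, abundance_path, report_path) {
  x$abundance %>%
    select(reference_id = "ref_id", "mbp", "coverage",
           relative_abundance = "ra") %>%
    readr::write_tsv(abundance_path)
  r <- x$report
  reasons <- r$discard_reasons
  if (length(reasons) > 0)
    names(reasons) <- paste0("discarded_", names(reasons))
  flat <- c(
    n_pairs = r$n_pairs, n_unique = r$n_unique, n_tied = r$n_tied,
    n_discarded = r$n_discarded,
    vapply(reasons, as.character, character(1)),
    n_tie_groups = r$n_tie_groups,
    n_zero_unique_groups_resolved = r$n_zero_unique_groups_resolved,
    flagged_groups = paste(r$flagged_groups, collapse = ";"),
    degenerate = as.character(r$degenerate),
    min_ra = r$min_ra, thresholded = as.character(r$thresholded))
  writeLines(paste(names(flat), unname(flat), sep = "\t"), report_path)
  invisible(x)
}
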