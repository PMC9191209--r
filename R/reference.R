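#' Build and validate a reference set
#'
#' A reference set holds the `n` candidate genomes a pooled sample is
#' quantified against: one row per genome with its identifier, nucleotide
#' sequence and length `g` in bases.  Genome identity must be unique and
#' sequences non-empty; sequences are stored upper-case.
#'
#' @param sequence Character vector of genome sequences (alphabet
#'   `A/C/G/T/N`; other letters are tolerated but always count as
#'   mismatches during alignment).
#' @param ref_id Character vector of unique genome identifiers; defaults to
#'   `names(sequence)`.
#'
#' @return A tibble of class `reference_set` with columns `ref_id`,
#'   `sequence` and `length_bp`.
#' @examples
#' reference_set(c(A = "ACGTACGT", B = "ACGTTTTTACGT"))
#' @export
reference_set <- function(sequence, ref_id = names(sequence)) {
  if (is.null(ref_id)) stopf("`ref_id` is required when `sequence` is unnamed")
  refs <- tibble(ref_id = as.character(ref_id),
                 sequence = toupper(as.character(sequence)),
                 length_bp = nchar(sequence))
  validate_reference_set(refs)
}

#' Validate reference-set invariants
#'
#' Checks that a table of genomes is a usable reference set: at least one
#' genome, pairwise-distinct non-empty identifiers, non-empty sequences,
#' and `length_bp` equal to the sequence length.
#'
#' @param refs A data frame with columns `ref_id`, `sequence` and
#'   optionally `length_bp` (recomputed if absent).
#' @return The validated `reference_set` tibble, invisibly usable in
#'   pipes.
#' @export
validate_reference_set <- function(refs) {
  refs <- as_tibble(refs)
  if (nrow(refs) < 1L) stopf("a reference set needs at least one genome")
  if (!all(c("ref_id", "sequence") %in% names(refs)))
    stopf("reference set needs `ref_id` and `sequence` columns")
  if (!("length_bp" %in% names(refs))) refs$length_bp <- nchar(refs$sequence)
  if (anyDuplicated(refs$ref_id))
    stopf("duplicate ref_id: %s",
          paste(unique(refs$ref_id[duplicated(refs$ref_id)]), collapse = ", "))
  if (any(!nzchar(refs$ref_id)) || anyNA(refs$ref_id))
    stopf("every ref_id must be a non-empty string")
  if (any(refs$length_bp < 1L))
    stopf("empty sequence for ref_id: %s",
          paste(refs$ref_id[refs$length_bp < 1L], collapse = ", "))
  if (any(refs$length_bp != nchar(refs$sequence)))
    stopf("length_bp inconsistent with sequence length")
  class(refs) <- unique(c("reference_set", class(refs)))
  refs
}

#' Read reference genomes from FASTA files
#'
#' Each FASTA file is one genome; multi-record files (multi-contig
#' references) are concatenated, so `g` is the summed record length and
#' all records share the genome's identifier.  The identifier defaults to
#' the file name without extensions.
#'
#' @param paths Character vector of FASTA paths (gzip accepted).
#' @param ref_id Optional identifiers, one per file.
#' @return A `reference_set` tibble.
#' @export
read_reference_fasta <- function(paths, ref_id = NULL) {
  if (is.null(ref_id))
    ref_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths))
  seqs <- vapply(paths, function(p) {
    recs <- Biostrings::readDNAStringSet(p)
    paste(as.character(recs), collapse = "")
  }, character(1))
  reference_set(unname(seqs), ref_id = ref_id)
}

#' Write a reference set to FASTA
#'
#' @param refs A `reference_set`.
#' @param dir Output directory (created if needed); one file per genome,
#'   named `<ref_id>.fasta`.
#' @return Invisibly, the written paths named by `ref_id`.
#' @export
write_reference_fasta <- function(refs, dir) {
  refs <- validate_reference_set(refs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(refs$ref_id, ".fasta"))
  for (i in seq_len(nrow(refs))) {
    x <- Biostrings::DNAStringSet(refs$sequence[i])
    names(x) <- refs$ref_id[i]
    Biostrings::writeXStringSet(x, paths[i])
  }
  invisible(setNames(paths, refs$ref_id))
}
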