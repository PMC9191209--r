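# Shared fixtures, built in code.

# the two-reference worked example: equal 100 bp genomes, 3 pairs unique to
# A, 1 unique to B, 4 tied {A,B}, 20 mapped bases per pair
worked_example_assignments <- function() {
  asn <- tibble::tibble(
    pair_id = sprintf("p%d", 1:8),
    status = c(rep("unique_perfect", 4), rep("tied_perfect", 4)),
    refs = c(rep(list("A"), 3), list("B"), rep(list(c("A", "B")), 4)),
    reason = NA_character_,
    mapped_bases = 20)
  class(asn) <- unique(c("assignment_tbl", class(asn)))
  asn
}

worked_example_refs <- function() {
  withr::with_seed(421, {
    a <- random_dna(100)
    # B shares positions 41-100 with A (tied region), differs in 1-40
    b40 <- chartr("ACGT", "GTAC", substr(a, 1, 40))
    b <- paste0(b40, substr(a, 41, 100))
    reference_set(c(A = a, B = b))
  })
}

# an end-to-end read fixture realising the worked example: mates of 10 bp,
# inner insert 0 (20 mapped bases per pair)
worked_example_reads <- function(refs) {
  frag <- function(seq, start) {   # 20 bp fragment, 0-based start
    f <- substr(seq, start + 1, start + 20)
    list(mate1 = substr(f, 1, 10),
         mate2 = reverse_complement(substr(f, 11, 20)))
  }
  a <- refs$sequence[refs$ref_id == "A"]
  b <- refs$sequence[refs$ref_id == "B"]
  pairs <- c(
    lapply(c(0, 10, 20), frag, seq = a),   # unique to A (divergent region)
    lapply(5, frag, seq = b),              # unique to B
    lapply(c(45, 55, 65, 75), frag, seq = a))  # shared region: tied {A,B}
  tibble::tibble(
    pair_id = sprintf("p%d", seq_along(pairs)),
    mate1 = vapply(pairs, `[[`, "", "mate1"),
    mate2 = vapply(pairs, `[[`, "", "mate2"))
}

# minimal SAM text for one reference; records = list of c(qname, flag,
# rname, pos1based, cigar, seq, nm or NA, as or NA)
make_sam <- function(path, sq_name, sq_len, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sq_name, sq_len))
  body <- vapply(records, function(r) {
    line <- paste(r$qname, r$flag, r$rname, r$pos, "60", r$cigar,
                  "=", "1", "0", r$seq, "*", sep = "\t")
    if (!is.null(r$nm)) line <- paste0(line, "\tNM:i:", r$nm)
    if (!is.null(r$as)) line <- paste0(line, "\tAS:i:", r$as)
    line
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
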