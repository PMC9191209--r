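# Independent oracles, deliberately written long-hand with base-R loops so
# they share no code path with the package implementation.

# --- quantification oracle -------------------------------------------------
# pairs: list of character vectors = the set of references each perfect
# pair matched; bases: mapped bases per pair.  Applies the two-phase
# procedure pair-set by pair-set.
oracle_quantify <- function(pair_sets, bases, ref_ids, g) {
  stopifnot(length(pair_sets) == length(bases))
  u <- setNames(numeric(length(ref_ids)), ref_ids)
  for (i in seq_along(pair_sets)) {
    s <- pair_sets[[i]]
    if (length(s) == 1L) u[s] <- u[s] + bases[i]
  }
  gl <- setNames(g, ref_ids)
  ra_of <- function(mbp) {
    cov <- mbp / gl
    if (sum(cov) > 0) cov / sum(cov) else cov * 0
  }
  ra1 <- ra_of(u)

  # collect tie groups in canonical order
  tied <- which(lengths(pair_sets) >= 2L)
  keys <- vapply(tied, function(i)
    paste(sort(pair_sets[[i]]), collapse = "\t"), character(1))
  group_keys <- sort(unique(keys))
  group_bases <- vapply(group_keys, function(k)
    sum(bases[tied[keys == k]]), numeric(1))

  # phase 1: groups with a mix of supported and unsupported members
  mbp2 <- u
  unresolved <- character()
  for (k in group_keys) {
    members <- strsplit(k, "\t", fixed = TRUE)[[1]]
    supp <- members[u[members] > 0]
    if (length(supp) > 0 && length(supp) < length(members)) {
      w <- ra1[supp] / sum(ra1[supp])
      mbp2[supp] <- mbp2[supp] + group_bases[[k]] * w
    } else {
      unresolved <- c(unresolved, k)
    }
  }
  ra2 <- ra_of(mbp2)

  # phase 2: remaining groups proportional to current RA (equal when all 0)
  mbp3 <- mbp2
  for (k in unresolved) {
    members <- strsplit(k, "\t", fixed = TRUE)[[1]]
    w <- ra2[members]
    if (sum(w) > 0) {
      mbp3[members] <- mbp3[members] + group_bases[[k]] * w / sum(w)
    } else {
      mbp3[members] <- mbp3[members] + group_bases[[k]] / length(members)
    }
  }
  list(mbp_unique = u, ra_unique = ra1, mbp_final = mbp3,
       ra_final = ra_of(mbp3))
}

# run the package quantifier on the same abstract instance
pkg_quantify_instance <- function(pair_sets, bases, refs, min_ra = 0) {
  asn <- tibble::tibble(
    pair_id = sprintf("p%04d", seq_along(pair_sets)),
    status = ifelse(lengths(pair_sets) == 1L, "unique_perfect",
                    "tied_perfect"),
    refs = lapply(pair_sets, sort),
    reason = NA_character_,
    mapped_bases = bases)
  class(asn) <- unique(c("assignment_tbl", class(asn)))
  quantify(asn, refs, min_ra = min_ra)
}

# random abstract instance: <= 3 refs, <= 30 pairs
random_instance <- function(n_refs = sample(1:3, 1),
                            n_pairs = sample(1:30, 1)) {
  ref_ids <- LETTERS[seq_len(n_refs)]
  g <- sample(100:5000, n_refs, replace = TRUE)
  pair_sets <- lapply(seq_len(n_pairs), function(i) {
    k <- sample(seq_len(n_refs), 1)
    sample(ref_ids, k)
  })
  bases <- sample(20:500, n_pairs, replace = TRUE)
  list(pair_sets = pair_sets, bases = bases, ref_ids = ref_ids, g = g)
}

# --- aligner oracle --------------------------------------------------------
# every-offset scan for all full-length ungapped placements with Hamming
# distance <= max_mm, both strands
brute_placements <- function(genome, read, max_mm) {
  gc <- strsplit(toupper(genome), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  one_strand <- function(rd, strand) {
    rc <- strsplit(rd, "")[[1]]
    L <- length(rc); G <- length(gc)
    if (L > G) stop("read longer than genome")
    res <- list()
    for (off in 0:(G - L)) {
      win <- gc[(off + 1):(off + L)]
      mm <- sum(win != rc | !(rc %in% acgt))
      if (mm <= max_mm)
        res[[length(res) + 1]] <- data.frame(pos = off, strand = strand,
                                            mismatches = mm)
    }
    do.call(rbind, res)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_read <- paste(rev(unname(
    comp[strsplit(toupper(read), "")[[1]]])), collapse = "")
  out <- rbind(one_strand(toupper(read), "+"), one_strand(rc_read, "-"))
  if (is.null(out))
    out <- data.frame(pos = integer(), strand = character(),
                      mismatches = integer())
  out[order(out$strand, out$pos), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
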