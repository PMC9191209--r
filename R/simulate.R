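# synthetic mixtures: random genomes, substitution-only mutants, and
# paired-end read simulation with a uniform per-base substitution error
# rate.  Ground truth is kept in relative-coverage units - the quantity
# the quantifier's RA estimates - so expected-vs-observed error is well
# defined even when genome lengths differ.

#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T sequence, reproducible under `seed`.
#'
#' @param length Genome length in bases, `> 0`.
#' @param ref_id Identifier for the genome.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A one-row `reference_set`.
#' @export
generate_genome <- function(length, ref_id = "genome1", seed = NULL) {
  if (length < 1) stopf("`length` must be positive")
  seq <- with_seed_maybe(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
  reference_set(setNames(seq, ref_id))
}

#' Derive a substitution-only mutant of a genome
#'
#' Substitutes exactly `round(divergence * length)` positions, chosen
#' without replacement, each to a different base; indels are deliberately
#' not modelled so pairwise identity and tied-read fractions have closed
#' forms.
#'
#' @param parent A one-row `reference_set`.
#' @param divergence Substitution fraction in `[0, 1]`.
#' @param ref_id Identifier for the mutant.
#' @param seed Optional integer seed.
#' @return A one-row `reference_set`; attribute `realized_identity` gives
#'   `1 - n_substituted / length`.
#' @export
mutate_genome <- function(parent, divergence, ref_id = NULL, seed = NULL) {
  if (divergence < 0 || divergence > 1)
    stopf("`divergence` must be in [0, 1]")
  parent <- validate_reference_set(parent)
  if (nrow(parent) != 1L) stopf("`parent` must be a single genome")
  if (is.null(ref_id)) ref_id <- paste0(parent$ref_id, "_mut")
  L <- parent$length_bp
  n_sub <- round(divergence * L)
  seq <- with_seed_maybe(seed, {
    s <- strsplit(parent$sequence, "", fixed = TRUE)[[1]]
    if (n_sub > 0) {
      at <- sample.int(L, n_sub)
      bases <- c("A", "C", "G", "T")
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    paste(s, collapse = "")
  })
  out <- reference_set(setNames(seq, ref_id))
  attr(out, "realized_identity") <- 1 - n_sub / L
  out
}

#' Ungapped pairwise identity of two equal-length genomes
#'
#' Fraction of matching positions; a plumbing utility sufficient for
#' substitution-only mutants (gapped global alignment is out of scope).
#'
#' @param a,b One-row `reference_set`s or sequence strings of equal
#'   length.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  sa <- as_genome(a); sb <- as_genome(b)
  if (nchar(sa) != nchar(sb))
    stopf("sequences differ in length (%d vs %d); gapped comparison is not supported",
          nchar(sa), nchar(sb))
  mean(strsplit(sa, "", fixed = TRUE)[[1]] ==
         strsplit(sb, "", fixed = TRUE)[[1]])
}

#' Simulate a paired-end sequencing mixture
#'
#' Draws the number of read pairs per genome multinomially with weights
#' proportional to (target relative coverage x genome length), then for
#' each pair: a uniform fragment start, forward-reverse orientation with
#' the forward mate chosen at random, an inner insert from a truncated
#' normal, and per-base substitution errors at the configured rate.
#' Ground truth records the target relative coverages.
#'
#' @param refs A `reference_set`.
#' @param proportions Target relative coverages, one per reference
#'   (non-negative, summing to 1; zero marks an absent genome).
#' @param n_pairs Total read pairs to simulate (default 100000).
#' @param read_length Read length in bp (default 250).
#' @param insert_mean,insert_sd Inner insert (gap between mates) mean and
#'   sd in bp; draws are truncated to `[0, insert_max]` and to fragments
#'   that fit the genome.
#' @param insert_max Upper truncation for the inner insert (default 1000).
#' @param error_rate Per-base substitution error probability (default
#'   0.001).
#' @param seed Optional integer seed; fixes all downstream randomness.
#' @return An object of class `mixture_sim`: list with `reads` (tibble
#'   `pair_id`, `source`, `mate1`, `mate2`, `start`, `insert`,
#'   `mate1_forward`), `truth` (tibble `ref_id`, `true_ra`, `n_pairs`)
#'   and `config`.
#' @export
simulate_mixture <- function(refs, proportions, n_pairs = 100000L,
                             read_length = 250L, insert_mean = 150,
                             insert_sd = 50, insert_max = 1000,
                             error_rate = 0.001, seed = NULL) {
  refs <- validate_reference_set(refs)
  if (length(proportions) != nrow(refs))
    stopf("`proportions` must have one entry per reference (%d != %d)",
          length(proportions), nrow(refs))
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stopf("`proportions` must be non-negative and sum to 1")
  if (any(proportions > 0 & refs$length_bp < 2L * read_length))
    stopf("read length too large for a present genome")

  with_seed_maybe(seed, {
    w <- proportions * refs$length_bp
    counts <- as.integer(rmultinom(1L, n_pairs, w))

    per_ref <- vector("list", nrow(refs))
    for (i in seq_len(nrow(refs))) {
      k <- counts[i]
      if (k == 0L) next
      g <- refs$length_bp[i]
      max_inner <- min(insert_max, g - 2L * read_length)
      inner <- integer(0)
      while (length(inner) < k) {                  # truncated normal
        draw <- round(rnorm(k, insert_mean, insert_sd))
        inner <- c(inner, draw[draw >= 0 & draw <= max_inner])
      }
      inner <- inner[seq_len(k)]
      frag <- 2L * read_length + inner
      start <- floor(runif(k, min = 0, max = g - frag + 1))  # 0-based
      fwd <- substring(refs$sequence[i], start + 1L,
                       start + read_length)
      rev <- revcomp_cpp(substring(refs$sequence[i],
                                   start + frag - read_length + 1L,
                                   start + frag))
      m1fwd <- runif(k) < 0.5
      per_ref[[i]] <- tibble(
        source = refs$ref_id[i],
        mate1 = if_else(m1fwd, fwd, rev),
        mate2 = if_else(m1fwd, rev, fwd),
        start = as.integer(start), insert = inner,
        mate1_forward = m1fwd)
    }
    reads <- bind_rows(per_ref)
    if (nrow(reads) > 0) {
      reads$pair_id <- sprintf("pair%06d", seq_len(nrow(reads)))
      reads <- reads %>% select("pair_id", dplyr::everything())
      if (error_rate > 0) {
        for (col in c("mate1", "mate2")) {
          n_err <- rbinom(nrow(reads), read_length, error_rate)
          pos <- lapply(n_err, function(e)
            if (e > 0) sample.int(read_length, e) else integer(0))
          reads[[col]] <- inject_substitutions_cpp(reads[[col]], pos)
        }
      }
    } else {
      reads <- tibble(pair_id = character(), source = character(),
                      mate1 = character(), mate2 = character(),
                      start = integer(), insert = integer(),
                      mate1_forward = logical())
    }

    structure(
      list(reads = reads,
           truth = tibble(ref_id = refs$ref_id, true_ra = proportions,
                          n_pairs = counts),
           config = list(n_pairs = n_pairs, read_length = read_length,
                         insert_mean = insert_mean, insert_sd = insert_sd,
                         insert_max = insert_max, error_rate = error_rate,
                         seed = seed)),
      class = "mixture_sim")
  })
}

#' @export
print.mixture_sim <- function(x, ...) {
  cat(sprintf("<mixture_sim> %d pairs from %d genomes (%d present)\n",
              nrow(x$reads), nrow(x$truth), sum(x$truth$true_ra > 0)))
  print(x$truth)
  invisible(x)
}

#' Write a simulated mixture to FASTQ, truth TSV and config
#'
#' Writes standard 4-line FASTQ mates (`<prefix>_R1.fastq[.gz]`,
#' `<prefix>_R2...`) with a constant placeholder quality, the ground truth
#' as TSV (`reference_id`, `true_relative_abundance`, `n_pairs`), and the
#' simulation config as YAML.
#'
#' @param sim A `mixture_sim`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sample"`).
#' @param gzip Compress the FASTQ files (default `FALSE`).
#' @return Invisibly, a named list of the written paths.
#' @export
write_mixture <- function(sim, dir, prefix = "sample", gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(prefix, "_R1", ext))
  p2 <- file.path(dir, paste0(prefix, "_R2", ext))
  write_fastq <- function(ids, seqs, path, mate) {
    qual <- strrep("I", nchar(seqs))
    lines <- as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", qual))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
  }
  write_fastq(sim$reads$pair_id, sim$reads$mate1, p1, 1L)
  write_fastq(sim$reads$pair_id, sim$reads$mate2, p2, 2L)
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  sim$truth %>%
    select(reference_id = "ref_id", true_relative_abundance = "true_ra",
           "n_pairs") %>%
    readr::write_tsv(truth_path)
  config_path <- file.path(dir, paste0(prefix, "_sim_config.yaml"))
  yaml::write_yaml(sim$config, config_path)
  invisible(list(fastq1 = p1, fastq2 = p2, truth = truth_path,
                 config = config_path))
}

#' Read paired FASTQ files into mate vectors
#'
#' @param fastq1,fastq2 Paths to the two mate files (gzip accepted).
#' @return Tibble with `pair_id` (FASTQ name stripped of a trailing
#'   `/1`/`/2`), `mate1`, `mate2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2))
    stopf("mate files differ in read count (%d vs %d)",
          length(r1), length(r2))
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(names(r1)); id2 <- strip(names(r2))
  if (!identical(id1, id2)) stopf("mate files are not in the same order")
  tibble(pair_id = id1, mate1 = unname(as.character(r1)),
         mate2 = unname(as.character(r2)))
}
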