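# the in-silico benchmark: a 10-genome panel of one ancestor plus nine
# substitution-only mutants spanning ~90-99.9% pairwise identity, mixed in
# known ratios and sequenced in silico, then quantified and scored.
# All sizes here are the package's study conditions (see the methods
# vignette).

#' Default benchmark reference panel
#'
#' One random ancestor genome plus mutants at the given divergences,
#' emulating a panel of related genomes spanning identities from ~90% to
#' 99.9%.
#'
#' @param genome_length Genome length in bp (default 40000).
#' @param divergences Substitution fractions for the mutants.
#' @param seed Optional integer seed.
#' @return A `reference_set` with `length(divergences) + 1` genomes named
#'   `G01`, `G02`, ...
#' @export
benchmark_references <- function(genome_length = 40000L,
                                 divergences = c(0.001, 0.002, 0.005,
                                                 0.01, 0.02, 0.03, 0.05,
                                                 0.07, 0.10),
                                 seed = NULL) {
  with_seed_maybe(seed, {
    anc <- generate_genome(genome_length, ref_id = "G01")
    muts <- purrr::imap(divergences, function(d, i)
      mutate_genome(anc, d, ref_id = sprintf("G%02d", i + 1L)))
    validate_reference_set(bind_rows(c(list(anc), muts)))
  })
}

# proportions for k present genomes: minimum 1%, skewed spread; every
# third sample pins one genome at 50% and another at 1% so the extremes
# of the tested range are always exercised
panel_proportions <- function(k, pin_extremes = FALSE) {
  if (k == 1L) return(1)
  if (pin_extremes && k >= 3L) {
    rest <- rexp(k - 2L)
    p <- c(0.50, 0.01,
           0.01 + (0.49 - 0.01 * (k - 2L)) * rest / sum(rest))
    return(sample(p))
  }
  w <- rexp(k)
  p <- 0.01 + (1 - 0.01 * k) * w / sum(w)
  sample(p)
}

#' Design a benchmark mixture panel
#'
#' Builds the sample sheet for the in-silico benchmark: `n_full` samples
#' where all genomes are present, plus `n_partial` samples where 1-8
#' genomes are absent (proportion exactly zero) while the full reference
#' set is still supplied to the quantifier.  Present-genome proportions
#' range from 1% up to ~50%.
#'
#' @param refs The `reference_set` being benchmarked.
#' @param n_full Number of all-present samples (default 12).
#' @param n_partial Number of partial-absence samples (default 21).
#' @param seed Optional integer seed.
#' @return Tibble with `sample_id`, `design` (`full`/`partial`),
#'   `n_present` and a `proportions` list-column (one named vector per
#'   sample, summing to 1, zeros marking absent genomes).
#' @export
benchmark_panel <- function(refs, n_full = 12L, n_partial = 21L,
                            seed = NULL) {
  refs <- validate_reference_set(refs)
  n <- nrow(refs)
  with_seed_maybe(seed, {
    full <- purrr::map(seq_len(n_full), function(i) {
      p <- panel_proportions(n, pin_extremes = (i %% 3L == 0L))
      setNames(p, refs$ref_id)
    })
    absent_counts <- rep(seq_len(min(8L, n - 2L)),
                         length.out = n_partial)
    partial <- purrr::map(absent_counts, function(k) {
      absent <- sample(refs$ref_id, k)
      present <- setdiff(refs$ref_id, absent)
      p <- setNames(numeric(n), refs$ref_id)
      p[present] <- panel_proportions(length(present))
      p
    })
    props <- c(full, partial)
    tibble(
      sample_id = sprintf("s%02d", seq_along(props)),
      design = rep(c("full", "partial"), c(n_full, n_partial)),
      n_present = vapply(props, function(p) sum(p > 0), integer(1)),
      proportions = props)
  })
}

#' Simulate, quantify and score a benchmark panel
#'
#' For each panel sample: simulate reads, run the full in-memory pipeline
#' (competitive alignment, merge/filter, classification, two-phase
#' quantification) and join the result with the simulation truth.
#'
#' @param refs The `reference_set`.
#' @param panel Sample sheet from [benchmark_panel()].
#' @param n_pairs Read pairs per sample (default 30000).
#' @param read_length Read length in bp (default 250).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param max_mismatches Aligner mismatch budget (default 4).
#' @param seed Optional integer seed fixing all per-sample simulation
#'   seeds.
#' @return Evaluation records as [evaluate_abundances()], across all
#'   samples.
#' @export
run_benchmark <- function(refs, panel, n_pairs = 30000L,
                          read_length = 250L, error_rate = 0.001,
                          max_mismatches = 4L, seed = NULL) {
  refs <- validate_reference_set(refs)
  sample_seeds <- with_seed_maybe(seed,
    sample.int(.Machine$integer.max, nrow(panel)))
  res <- purrr::map(seq_len(nrow(panel)), function(i) {
    sim <- simulate_mixture(refs, unname(panel$proportions[[i]]),
                            n_pairs = n_pairs,
                            read_length = read_length,
                            error_rate = error_rate,
                            seed = sample_seeds[i])
    q <- quantify_sample(refs, sim$reads$mate1, sim$reads$mate2,
                         pair_id = sim$reads$pair_id,
                         max_mismatches = max_mismatches)
    list(observed = q$abundance %>%
           mutate(sample_id = panel$sample_id[i]) %>%
           select("sample_id", "ref_id", "ra"),
         truth = sim$truth %>%
           mutate(sample_id = panel$sample_id[i]) %>%
           select("sample_id", "ref_id", "true_ra"))
  })
  evaluate_abundances(bind_rows(purrr::map(res, "observed")),
                      bind_rows(purrr::map(res, "truth")))
}
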