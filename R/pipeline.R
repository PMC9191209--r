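# end-to-end orchestration: YAML configuration, per-sample quantification
# (internal aligner or external SAM/BAM ingest), simulation and evaluation
# entry points.  Samples are processed independently; results do not
# depend on execution order.

#' Quantify one sample in memory
#'
#' Full pipeline for one sample with the built-in aligner: competitive
#' alignment against every reference, merge-and-filter, classification,
#' two-phase quantification.
#'
#' @param refs A `reference_set`.
#' @param mate1,mate2 Read sequences of the pairs.
#' @param pair_id Optional pair identifiers.
#' @inheritParams align_read_pair
#' @inheritParams quantify
#' @return A `genome_quant`.
#' @export
quantify_sample <- function(refs, mate1, mate2, pair_id = NULL,
                            max_mismatches = 4L, min_insert = 0L,
                            max_insert = 1000L, min_ra = 0) {
  pa <- align_pairs(refs, mate1, mate2, pair_id = pair_id,
                    max_mismatches = max_mismatches,
                    min_insert = min_insert, max_insert = max_insert)
  quantify(classify_pairs(merge_and_filter(pa)), refs, min_ra = min_ra)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file:
#' ```yaml
#' output_dir: out
#' mapper: internal          # or external
#' max_mismatches: 4         # internal aligner only
#' min_insert: 0
#' max_insert: 1000
#' min_ra: 0                 # optional noise threshold
#' references:               # one FASTA per genome
#'   - refs/A.fasta
#'   - refs/B.fasta
#' samples:
#'   - id: s1
#'     fastq1: s1_R1.fastq.gz
#'     fastq2: s1_R2.fastq.gz
#'     alignments:           # external mode: one SAM/BAM per reference,
#'       - s1_A.sam          # in the order of `references`
#'       - s1_B.sam
#' ```
#' Every referenced path must exist at validation time; external mode
#' requires one alignment file per reference per sample.
#'
#' @param path Path to the YAML file; relative paths inside the file are
#'   resolved against its directory.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if_else(grepl("^/", p), p, file.path(base, p))

  defaults <- list(mapper = "internal", max_mismatches = 4L,
                   min_insert = 0L, max_insert = 1000L, min_ra = 0,
                   output_dir = "poolquant_out")
  cfg <- modifyList(defaults, cfg)
  if (!cfg$mapper %in% c("internal", "external"))
    stopf("`mapper` must be 'internal' or 'external'")
  if (is.null(cfg$references) || length(cfg$references) == 0L)
    stopf("config lists no reference genomes")
  if (is.null(cfg$samples) || length(cfg$samples) == 0L)
    stopf("config lists no samples")
  cfg$references <- resolve(unlist(cfg$references))
  missing <- cfg$references[!file.exists(cfg$references)]
  if (length(missing)) stopf("reference file not found: %s", missing[1])

  cfg$output_dir <- resolve(cfg$output_dir)
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    if (is.null(s$id)) stopf("sample %d has no `id`", i)
    if (cfg$mapper == "internal") {
      for (f in c("fastq1", "fastq2")) {
        if (is.null(s[[f]])) stopf("sample %s: missing `%s`", s$id, f)
        s[[f]] <- resolve(s[[f]])
        if (!file.exists(s[[f]]))
          stopf("sample %s: file not found: %s", s$id, s[[f]])
      }
    } else {
      if (is.null(s$alignments) ||
          length(s$alignments) != length(cfg$references))
        stopf("sample %s: external mode needs one alignment file per reference",
              s$id)
      s$alignments <- resolve(unlist(s$alignments))
      miss <- s$alignments[!file.exists(s$alignments)]
      if (length(miss))
        stopf("sample %s: alignment file not found: %s", s$id, miss[1])
    }
    cfg$samples[[i]] <- s
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the quantification pipeline over all configured samples
#'
#' For each sample: ingest or align reads per reference, merge and filter,
#' classify, quantify, and write `<id>_abundance.tsv` plus
#' `<id>_report.tsv` under the configured output directory.  A failing
#' sample is logged and skipped; the remaining samples still run.
#'
#' @param config A `pipeline_config` or a path to one.
#' @return Tibble with one row per sample: `sample_id`, `status`
#'   (`ok`/`error`), `message`, and a `result` list-column of
#'   `genome_quant` objects.
#' @export
run_quantify <- function(config) {
  if (is_string(config)) config <- read_pipeline_config(config)
  refs <- read_reference_fasta(config$references)
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)

  rows <- purrr::map(config$samples, function(s) {
    res <- tryCatch({
      if (config$mapper == "internal") {
        pairs <- read_fastq_pairs(s$fastq1, s$fastq2)
        q <- quantify_sample(refs, pairs$mate1, pairs$mate2,
                             pair_id = pairs$pair_id,
                             max_mismatches = config$max_mismatches,
                             min_insert = config$min_insert,
                             max_insert = config$max_insert,
                             min_ra = config$min_ra)
      } else {
        paths <- setNames(s$alignments, refs$ref_id)
        pa <- pair_alignments_from_sam(paths)
        q <- quantify(classify_pairs(merge_and_filter(pa)), refs,
                      min_ra = config$min_ra)
      }
      write_quant(q,
                  file.path(config$output_dir,
                            paste0(s$id, "_abundance.tsv")),
                  file.path(config$output_dir,
                            paste0(s$id, "_report.tsv")))
      list(status = "ok", message = "", result = q)
    }, error = function(e) {
      message(sprintf("sample %s failed: %s", s$id, conditionMessage(e)))
      list(status = "error", message = conditionMessage(e), result = NULL)
    })
    tibble(sample_id = s$id, status = res$status, message = res$message,
           result = list(res$result))
  })
  bind_rows(rows)
}

#' Simulate a mixture and write its files
#'
#' Exposes the simulator as a pipeline step: writes per-genome reference
#' FASTA, the paired FASTQ files, the ground-truth TSV and the echoed
#' config.
#'
#' @inheritParams simulate_mixture
#' @param dir Output directory.
#' @param prefix Sample file prefix.
#' @param gzip Compress FASTQ output.
#' @return The `mixture_sim`, invisibly; paths in attribute `paths`.
#' @export
run_simulate <- function(refs, proportions, dir, prefix = "sample",
                         n_pairs = 100000L, read_length = 250L,
                         error_rate = 0.001, gzip = FALSE, seed = NULL,
                         ...) {
  sim <- simulate_mixture(refs, proportions, n_pairs = n_pairs,
                          read_length = read_length,
                          error_rate = error_rate, seed = seed, ...)
  paths <- write_mixture(sim, dir, prefix = prefix, gzip = gzip)
  paths$references <- write_reference_fasta(refs, file.path(dir, "refs"))
  attr(sim, "paths") <- paths
  invisible(sim)
}

#' Evaluate written abundance tables against written truth tables
#'
#' Reads the quantifier's abundance TSVs and the simulator's truth TSVs
#' (named by sample), joins them and writes a per-record TSV and a
#' complexity-stratified summary TSV.
#'
#' @param abundance_paths,truth_paths Named character vectors,
#'   `sample_id -> path`; the two name sets must match.
#' @param dir Output directory for `evaluation_records.tsv` and
#'   `evaluation_summary.tsv`.
#' @return List with `records` and `summary` tibbles.
#' @export
run_evaluate <- function(abundance_paths, truth_paths, dir = NULL) {
  if (is.null(names(abundance_paths)) || is.null(names(truth_paths)))
    stopf("abundance and truth paths must be named by sample")
  unmatched <- c(setdiff(names(abundance_paths), names(truth_paths)),
                 setdiff(names(truth_paths), names(abundance_paths)))
  if (length(unmatched))
    stopf("samples without a counterpart: %s",
          paste(unique(unmatched), collapse = ", "))
  observed <- purrr::imap(abundance_paths, function(p, id)
    readr::read_tsv(p, show_col_types = FALSE) %>%
      mutate(sample_id = id) %>%
      select("sample_id", ref_id = "reference_id",
             ra = "relative_abundance")) %>%
    bind_rows()
  truth <- purrr::imap(truth_paths, function(p, id)
    readr::read_tsv(p, show_col_types = FALSE) %>%
      mutate(sample_id = id) %>%
      select("sample_id", ref_id = "reference_id",
             true_ra = "true_relative_abundance")) %>%
    bind_rows()
  records <- evaluate_abundances(observed, truth)
  summary <- summarize_panel(records)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_tsv(records, file.path(dir, "evaluation_records.tsv"))
    readr::write_tsv(summary, file.path(dir, "evaluation_summary.tsv"))
  }
  list(records = records, summary = summary)
}
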