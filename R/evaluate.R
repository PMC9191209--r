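# evaluation against ground truth: per-cell quantification error,
# false-negative / false-positive calls, and complexity-stratified panel
# summaries.  Errors are stored as fractions; human-facing summaries are
# expressed in percent only at the presentation layer.

#' Absolute quantification error
#'
#' `|expected - observed|` on relative-abundance values.
#'
#' @param expected,observed Relative abundances in `[0, 1]` (vectorised).
#' @return Absolute errors in `[0, 1]`.
#' @export
quantification_error <- function(expected, observed) {
  if (any(expected < 0 | expected > 1) || any(observed < 0 | observed > 1))
    stopf("relative abundances must lie in [0, 1]")
  abs(expected - observed)
}

#' Join observed abundances with ground truth
#'
#' Builds one evaluation record per (sample, reference) cell: expected and
#' observed RA, absolute error, presence truth (`expected > 0`) and call
#' (`observed > 0`), plus the sample's mixture complexity (number of
#' genomes truly present).
#'
#' @param observed Tibble with `sample_id`, `ref_id`, `ra`.
#' @param truth Tibble with `sample_id`, `ref_id`, `true_ra`.
#' @return Tibble of evaluation records; errors if any (sample,
#'   reference) key is unmatched on either side.
#' @export
evaluate_abundances <- function(observed, truth) {
  obs_k <- paste(observed$sample_id, observed$ref_id)
  tru_k <- paste(truth$sample_id, truth$ref_id)
  if (length(setdiff(obs_k, tru_k)) > 0 || length(setdiff(tru_k, obs_k)) > 0)
    stopf("unmatched (sample, reference) keys: %s",
          paste(head(c(setdiff(obs_k, tru_k), setdiff(tru_k, obs_k)), 5),
                collapse = ", "))
  truth %>%
    left_join(observed, by = c("sample_id", "ref_id")) %>%
    mutate(expected = .data$true_ra, observed = .data$ra,
           abs_error = quantification_error(.data$expected, .data$observed),
           present = .data$expected > 0,
           called = .data$observed > 0) %>%
    group_by(.data$sample_id) %>%
    mutate(n_present = sum(.data$present)) %>%
    ungroup() %>%
    select("sample_id", "ref_id", "expected", "observed", "abs_error",
           "present", "called", "n_present")
}

#' Count false negatives and collect false-positive values
#'
#' A false negative is a truly present genome assigned exactly zero RA (no
#' epsilon: the all-or-nothing perfect-read mechanism means any assigned
#' base yields a positive RA).  A false positive is any positive RA
#' assigned to an absent genome; the assigned values are returned so their
#' maximum and median can be reported.
#'
#' @param records Evaluation records from [evaluate_abundances()].
#' @return List with `n_false_negative`, `false_positive_values`,
#'   `n_true_positive`, `n_correct_absence`, `n_records`.
#' @export
classify_calls <- function(records) {
  fn <- records$present & !records$called
  fp <- !records$present & records$called
  list(
    n_false_negative = sum(fn),
    false_positive_values = records$observed[fp],
    n_true_positive = sum(records$present & records$called),
    n_correct_absence = sum(!records$present & !records$called),
    n_records = nrow(records))
}

#' Summarise a panel by mixture complexity
#'
#' Per complexity group (number of genomes present in the sample) and
#' overall: median and maximum absolute error, false-negative count,
#' maximum and median false-positive RA, and cell counts.
#'
#' @param records Evaluation records from [evaluate_abundances()].
#' @return Tibble with one row per complexity plus an `overall` row;
#'   errors as fractions, and `*_pct` companions in percentage points.
#' @export
summarize_panel <- function(records) {
  if (nrow(records) == 0L) stopf("no evaluation records")
  one <- function(d, label) {
    calls <- classify_calls(d)
    fpv <- calls$false_positive_values
    abs_obs <- d$observed[!d$present]
    tibble(
      group = label,
      n_cells = nrow(d),
      n_present = sum(d$present),
      n_absent = sum(!d$present),
      median_error = median(d$abs_error),
      max_error = max(d$abs_error),
      n_false_negative = calls$n_false_negative,
      n_false_positive = length(fpv),
      max_false_positive = if (length(abs_obs)) max(abs_obs) else NA_real_,
      median_false_positive = if (length(abs_obs)) median(abs_obs)
                              else NA_real_)
  }
  groups <- records %>%
    group_by(.data$n_present) %>%
    dplyr::group_map(~ one(.x, as.character(.y$n_present))) %>%
    bind_rows()
  out <- bind_rows(groups, one(records, "overall"))
  out %>%
    mutate(median_error_pct = 100 * .data$median_error,
           max_error_pct = 100 * .data$max_error,
           max_false_positive_pct = 100 * .data$max_false_positive,
           median_false_positive_pct = 100 * .data$median_false_positive)
}

#' Plot error distributions by mixture complexity
#'
#' @param records Evaluation records from [evaluate_abundances()].
#' @return A ggplot boxplot of per-cell absolute error (in percentage
#'   points) against the number of genomes present.
#' @export
plot_error_by_complexity <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = factor(.data$n_present),
                               y = 100 * .data$abs_error)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.6) +
    ggplot2::labs(x = "genomes present in sample",
                  y = "absolute error (percentage points)") +
    ggplot2::theme_minimal()
}
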