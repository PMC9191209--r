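# internal helpers

# relative abundance from coverages; all-zero coverage yields all-zero RA
# (degenerate case handled explicitly by callers)
ra_from_coverage <- function(coverage) {
  s <- sum(coverage)
  if (s > 0) coverage / s else rep(0, length(coverage))
}

# run `expr` under a fixed seed when one is given, without disturbing the
# caller's RNG stream; seed = NULL uses (and advances) the current stream
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
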