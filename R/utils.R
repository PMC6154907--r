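# Internal helpers: input validation and seed plumbing.

.assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N} (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

.assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

# Derive a stage seed from a global seed so that pipeline stages can be rerun
# in isolation and still reproduce. Kept below 2^31 - 1.
.derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + as.integer(stage) * 7919L) %% 2147483587L
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.is_binary_labels <- function(labels) {
  all(labels %in% c("virus", "non_virus"))
}

# factor with fixed level order so "virus" probability columns are stable
.label_factor <- function(labels) {
  factor(labels, levels = c("non_virus", "virus"))
}
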