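#' Gini feature importance of the codon RSCU values
#'
#' A feature's importance in one tree is the sum of the Gini impurity
#' reductions at every split that uses it; per tree the importances are
#' normalized to sum to 1 so that every tree contributes equally, and the
#' report carries both the mean and the across-tree variance. The variance
#' matters because RSCU values of synonymous codons are strongly correlated
#' (within a two-codon family, almost perfectly anti-correlated) and
#' correlated features compete for importance between trees.
#'
#' Called on a feature table, `gini_importance()` follows the reporting
#' protocol of training a fresh forest of `n_trees` trees on the full dataset,
#' grown one bootstrap tree at a time so per-tree importances are observable.
#' Called on a fitted `viroscu_rf`, it normalizes the forest's aggregate
#' impurity importance (per-tree variance is then unavailable and reported as
#' `NA`). Any other model kind is an error.
#'
#' @param x A feature tibble (with `label` column) or a fitted `viroscu_rf`.
#' @param ... Passed to methods.
#' @param labels Optional label vector when `x` is a bare matrix/tibble
#'   without a `label` column.
#' @param n_trees Number of trees for the reporting forest (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `viroscu_importance` with one row per feature
#'   codon: `codon`, `amino_acid`, `family_size`, `mean_importance`,
#'   `variance` (across trees), sorted by decreasing mean importance.
#' @export
gini_importance <- function(x, ...) {
  UseMethod("gini_importance")
}

.importance_report <- function(mean_imp, var_imp, n_trees) {
  ct <- codon_table()
  ct <- ct[ct$is_feature, c("codon", "amino_acid", "family_size")]
  out <- ct |>
    mutate(
      mean_importance = unname(mean_imp[.data$codon]),
      variance = unname(var_imp[.data$codon])
    ) |>
    arrange(desc(.data$mean_importance))
  class(out) <- c("viroscu_importance", class(out))
  attr(out, "n_trees") <- n_trees
  out
}

#' @rdname gini_importance
#' @export
gini_importance.data.frame <- function(x, ..., labels = NULL, n_trees = 1000L, seed = 1L) {
  d <- .design_matrix(x, labels)
  n_trees <- .assert_scalar_int(n_trees, "n_trees")
  codons <- rscu_codon_order()
  per_tree <- matrix(0, nrow = n_trees, ncol = length(codons), dimnames = list(NULL, codons))
  for (t in seq_len(n_trees)) {
    fit <- ranger::ranger(
      x = d$X, y = d$y, num.trees = 1L, importance = "impurity",
      seed = .derive_seed(seed, t), num.threads = 1L
    )
    imp <- fit$variable.importance
    total <- sum(imp)
    per_tree[t, names(imp)] <- if (total > 0) imp / total else 0
  }
  .importance_report(
    colMeans(per_tree),
    apply(per_tree, 2L, var),
    n_trees
  )
}

#' @rdname gini_importance
#' @export
gini_importance.viroscu_rf <- function(x, ...) {
  imp <- x$fit$variable.importance
  total <- sum(imp)
  mean_imp <- if (total > 0) imp / total else imp
  var_imp <- setNames(rep(NA_real_, length(imp)), names(imp))
  .importance_report(mean_imp, var_imp, x$config$n_trees)
}

#' @export
gini_importance.default <- function(x, ...) {
  abort("Gini importance is defined for random forests (or feature tables), not for this object")
}

#' Group codon importances by amino-acid family
#'
#' Orders codons the way the importance figure is read: amino-acid families
#' with the most synonymous codons first (6, then 4, 3, 2), alphabetically by
#' amino acid within a family-size block, and includes each family's summed
#' importance.
#'
#' @param report A `viroscu_importance` tibble from [gini_importance()].
#' @return The report with columns `family_importance` added, rows reordered
#'   by `(family_size desc, amino_acid, codon)`.
#' @export
group_by_amino_acid <- function(report) {
  stopifnot(inherits(report, "viroscu_importance") ||
    all(c("codon", "amino_acid", "family_size", "mean_importance") %in% names(report)))
  report |>
    group_by(.data$amino_acid) |>
    mutate(family_importance = sum(.data$mean_importance)) |>
    ungroup() |>
    arrange(desc(.data$family_size), .data$amino_acid, .data$codon)
}

#' @export
tidy.viroscu_importance <- function(x, ...) {
  as_tibble(x)
}

#' Write an importance report
#'
#' TSV with columns `codon`, `amino_acid`, `family_size`, `mean_importance`,
#' `variance`.
#'
#' @param report A `viroscu_importance` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_table <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
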