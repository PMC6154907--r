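#' Leave-one-experiment-out folds
#'
#' One fold per sequencing experiment: the test set is every sample from that
#' experiment, the training set everything else. Because both strand samples
#' of a contig share an experiment, they always land in the same fold, so
#' within-run sequence similarity can never leak between training and test.
#'
#' @param features Feature tibble with an `experiment_id` column.
#' @return A tibble with one row per fold: `fold` (the held-out experiment
#'   ID), `train` and `test` (list columns of row indices into `features`).
#' @export
loeo_split <- function(features) {
  experiments <- sort(unique(features$experiment_id))
  if (length(experiments) < 2L) {
    abort("leave-one-experiment-out requires at least 2 distinct experiment IDs")
  }
  tibble(
    fold = experiments,
    train = map(experiments, function(e) which(features$experiment_id != e)),
    test = map(experiments, function(e) which(features$experiment_id == e))
  )
}

#' Stratified k-fold splits grouped by contig
#'
#' Near-equal partition into `k` folds, stratified by class so each fold's
#' prevalence tracks the global prevalence, and grouped by `contig_id` so the
#' two strand samples of a contig never straddle the train/test boundary.
#'
#' @param features Feature tibble with `label` (and optionally `contig_id`)
#'   columns.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffle.
#' @return A tibble with one row per fold: `fold` (`"fold01"` ...), `train`
#'   and `test` list columns of row indices.
#' @export
kfold_split <- function(features, k = 10L, seed = 1L) {
  k <- .assert_scalar_int(k, "k", min = 2L)
  n <- nrow(features)
  if (k > n) abort(sprintf("k = %d exceeds the number of samples (%d)", k, n))
  groups <- if ("contig_id" %in% names(features)) features$contig_id else as.character(seq_len(n))
  # group-level table: one label per contig (strands share a label)
  grp <- tibble(group = groups, label = features$label) |>
    group_by(.data$group) |>
    summarise(label = .data$label[1], .groups = "drop")
  if (k > nrow(grp)) {
    abort(sprintf("k = %d exceeds the number of contig groups (%d)", k, nrow(grp)))
  }
  assignment <- .with_seed(seed, {
    fold_of <- character(nrow(grp))
    fold_ids <- sprintf("fold%02d", seq_len(k))
    offset <- 0L
    for (cl in unique(grp$label)) {
      rows <- which(grp$label == cl)
      rows <- rows[sample.int(length(rows))]
      # continue dealing round-robin across classes so fold sizes stay even
      fold_of[rows] <- fold_ids[((seq_along(rows) - 1L + offset) %% k) + 1L]
      offset <- (offset + length(rows)) %% k
    }
    setNames(fold_of, grp$group)
  })
  sample_fold <- assignment[groups]
  fold_ids <- sprintf("fold%02d", seq_len(k))
  tibble(
    fold = fold_ids,
    train = map(fold_ids, function(f) unname(which(sample_fold != f))),
    test = map(fold_ids, function(f) unname(which(sample_fold == f)))
  )
}
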