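#' Cross-validated virus scoring
#'
#' Trains one classifier per fold on the training rows and scores the held-out
#' rows, producing the per-fold probability tables that every downstream
#' summary (micro/macro ROC, threshold metrics, precision-recall trade-off)
#' consumes.
#'
#' @param features Feature tibble from [extract_features()].
#' @param model `"random_forest"` or `"neural_net"`.
#' @param folds Fold tibble from [loeo_split()] or [kfold_split()]; defaults
#'   to leave-one-experiment-out on `features`.
#' @param config A [rf_config()] or [nn_config()] matching `model`; its seed
#'   is re-derived per fold so folds are independent but reproducible.
#' @param seed Integer seed controlling the per-fold seed derivation.
#' @param quiet Suppress per-fold progress messages.
#' @return A tibble of class `viroscu_cv` with one row per fold: `fold`,
#'   `scores` (list), `labels` (list), `n_samples`, `prevalence`.
#' @export
crossvalidate <- function(features, model = c("random_forest", "neural_net"),
                          folds = NULL, config = NULL, seed = 1L, quiet = TRUE) {
  model <- match.arg(model)
  if (is.null(folds)) folds <- loeo_split(features)
  if (is.null(config)) {
    config <- if (model == "random_forest") rf_config() else nn_config()
  }
  trainer <- switch(model,
    random_forest = train_random_forest,
    neural_net = train_neural_net
  )
  results <- vector("list", nrow(folds))
  for (i in seq_len(nrow(folds))) {
    train_rows <- features[folds$train[[i]], ]
    test_rows <- features[folds$test[[i]], ]
    fold_config <- config
    fold_config$seed <- .derive_seed(seed, i)
    fitted <- trainer(train_rows, config = fold_config)
    scores <- predict_proba(fitted, test_rows)
    if (!quiet) {
      inform(sprintf(
        "fold %s: %d train / %d test samples, prevalence %.3f",
        folds$fold[i], nrow(train_rows), nrow(test_rows), mean(test_rows$label == "virus")
      ))
    }
    results[[i]] <- tibble(
      fold = folds$fold[i],
      scores = list(scores),
      labels = list(test_rows$label),
      n_samples = nrow(test_rows),
      prevalence = mean(test_rows$label == "virus")
    )
  }
  out <- bind_rows(results)
  class(out) <- c("viroscu_cv", class(out))
  attr(out, "model") <- model
  attr(out, "config") <- config
  out
}

#' Summarize a cross-validation run
#'
#' Combines fold results into micro- and macro-averaged ROC curves and AUROCs,
#' per-class precision/recall/F1 at the stated threshold under both averaging
#' schemes, and the virus-class precision-recall trade-off curve.
#'
#' @param cv A `viroscu_cv` tibble from [crossvalidate()].
#' @param threshold Classification threshold for the per-class metrics.
#' @param pr_thresholds Threshold grid for the trade-off curve.
#' @return An object of class `viroscu_eval`: a list with elements `micro`,
#'   `macro`, `per_fold_auroc`, `micro_metrics`, `macro_metrics`,
#'   `pr_tradeoff`, `threshold`, `model`.
#' @export
summarize_evaluation <- function(cv, threshold = 0.5,
                                 pr_thresholds = seq(0, 1, by = 0.01)) {
  micro <- micro_average(cv)
  macro <- macro_average(cv)
  pooled_scores <- unlist(cv$scores)
  pooled_labels <- unlist(map(cv$labels, .binary_labels))
  micro_metrics <- classify_at_threshold(pooled_scores, pooled_labels, threshold)

  fold_y <- map(cv$labels, .binary_labels)
  per_fold_metrics <- map2(cv$scores, fold_y, classify_at_threshold, threshold = threshold)
  macro_metrics <- list_rbind(per_fold_metrics) |>
    group_by(.data$class) |>
    summarise(
      precision = mean(.data$precision[.data$support > 0]),
      recall = mean(.data$recall[.data$support > 0]),
      f1 = mean(.data$f1[.data$support > 0]),
      folds_with_support = sum(.data$support > 0),
      .groups = "drop"
    ) |>
    arrange(desc(.data$class))

  structure(
    list(
      model = attr(cv, "model") %||% "unknown",
      threshold = threshold,
      micro = micro,
      macro = macro,
      per_fold_auroc = macro$per_fold,
      micro_metrics = micro_metrics,
      macro_metrics = macro_metrics,
      pr_tradeoff = precision_recall_tradeoff(cv, pr_thresholds)
    ),
    class = "viroscu_eval"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.viroscu_eval <- function(x, ...) {
  cat(sprintf(
    "<viroscu evaluation: %d folds, micro AUROC %.3f, macro AUROC %.3f, threshold %.2f>\n",
    nrow(x$per_fold_auroc) + length(x$macro$dropped_folds),
    x$micro$auroc, x$macro$auroc, x$threshold
  ))
  print(x$micro_metrics)
  invisible(x)
}

#' Tidy a cross-validation evaluation
#'
#' @param x A `viroscu_eval` object.
#' @param ... Unused.
#' @return One row per fold with its AUROC, size and prevalence.
#' @export
tidy.viroscu_eval <- function(x, ...) {
  x$per_fold_auroc
}

#' One-row summary of a cross-validation evaluation
#'
#' @param x A `viroscu_eval` object.
#' @param ... Unused.
#' @return A tibble with micro/macro AUROC and virus-class precision/recall
#'   at the evaluation threshold.
#' @export
glance.viroscu_eval <- function(x, ...) {
  mv <- x$micro_metrics[x$micro_metrics$class == "virus", ]
  tibble(
    model = x$model,
    n_folds = nrow(x$per_fold_auroc) + length(x$macro$dropped_folds),
    micro_auroc = x$micro$auroc,
    macro_auroc = x$macro$auroc,
    threshold = x$threshold,
    virus_precision_micro = mv$precision,
    virus_recall_micro = mv$recall,
    virus_f1_micro = mv$f1
  )
}
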