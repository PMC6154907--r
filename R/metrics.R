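# ROC, micro/macro averaging, and threshold metrics. The ROC sweep and its
# trapezoid AUROC are implemented directly (tests cross-check them against a
# pairwise-concordance oracle and the pROC package).

# coerce labels to 0/1 with 1 = virus
.binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("virus", "non_virus"))) {
      abort("labels must be 'virus' or 'non_virus'")
    }
    as.integer(labels == "virus")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) abort("numeric labels must be 0/1")
    labels
  }
}

#' ROC curve and area under it
#'
#' Standard ROC by a descending-score threshold sweep with equal scores
#' grouped into one operating point; the area is computed by the trapezoid
#' rule, which handles ties as half-concordant.
#'
#' @param scores Numeric vector of `p(virus)` scores.
#' @param labels Labels (`virus`/`non_virus`, or 0/1 with 1 = virus).
#' @return A tibble of operating points with columns `threshold`, `fpr`,
#'   `tpr` (including the (0,0) and (1,1) endpoints), carrying the area in
#'   `attr(, "auroc")`. Use [auroc()] for the scalar alone.
#' @export
roc_curve <- function(scores, labels) {
  y <- .binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  # collapse tied scores into single operating points
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  curve <- tibble(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  attr(curve, "auroc") <- auc
  curve
}

#' @rdname roc_curve
#' @return `auroc()` returns the area as a single number.
#' @export
auroc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auroc")
}

.check_folds <- function(folds) {
  stopifnot(is.data.frame(folds), all(c("fold", "scores", "labels") %in% names(folds)))
  if (nrow(folds) < 1L) abort("at least one fold is required")
  folds
}

#' Micro-averaged ROC across cross-validation folds
#'
#' Pools all scores and labels across folds into one set before computing a
#' single ROC, so folds with more validation samples weigh more.
#'
#' @param folds Fold-result tibble with list columns `scores` and `labels`
#'   (as produced by [crossvalidate()]).
#' @return A list with `curve` (ROC tibble) and `auroc`.
#' @export
micro_average <- function(folds) {
  folds <- .check_folds(folds)
  scores <- unlist(folds$scores)
  labels <- unlist(map(folds$labels, .binary_labels))
  curve <- roc_curve(scores, labels)
  list(curve = curve, auroc = attr(curve, "auroc"))
}

#' Macro-averaged ROC across cross-validation folds
#'
#' Computes one ROC per fold and averages them with equal weight regardless
#' of fold size: the macro AUROC is the unweighted mean of per-fold AUROCs,
#' and the macro curve is the mean TPR interpolated on a fixed FPR grid
#' (vertical averaging). Folds whose test set lacks one of the classes have
#' no defined ROC and are dropped with a warning.
#'
#' @param folds Fold-result tibble (see [micro_average()]).
#' @param grid_points Number of FPR grid points for the averaged curve.
#' @return A list with `curve` (tibble `fpr`, `tpr`), `auroc`, `per_fold`
#'   (tibble `fold`, `auroc`, `n_samples`, `prevalence`) and `dropped_folds`.
#' @export
macro_average <- function(folds, grid_points = 101L) {
  folds <- .check_folds(folds)
  y_list <- map(folds$labels, .binary_labels)
  valid <- map_int(y_list, sum) > 0L & map_int(y_list, function(y) sum(1L - y)) > 0L
  if (any(!valid)) {
    warn(sprintf(
      "dropping %d fold(s) without both classes from macro averaging: %s",
      sum(!valid), paste(folds$fold[!valid], collapse = ", ")
    ))
  }
  if (!any(valid)) abort("no fold has both classes; macro average undefined")
  kept <- folds[valid, ]
  curves <- map2(kept$scores, kept$labels, roc_curve)
  grid <- seq(0, 1, length.out = grid_points)
  tpr_mat <- vapply(curves, function(cv) {
    approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(grid_points))
  per_fold <- tibble(
    fold = kept$fold,
    auroc = map_dbl(curves, attr, "auroc"),
    n_samples = map_int(kept$labels, length),
    prevalence = map_dbl(kept$labels, function(l) mean(.binary_labels(l)))
  )
  list(
    curve = tibble(fpr = grid, tpr = rowMeans(tpr_mat)),
    auroc = mean(per_fold$auroc),
    per_fold = per_fold,
    dropped_folds = folds$fold[!valid]
  )
}

#' Per-class precision, recall and F1 at a probability threshold
#'
#' A sample is predicted viral iff its score is greater than or equal to the
#' threshold. Precision, recall and F1 are reported separately for the virus
#' and non-virus classes, which is essential under strong class imbalance: a
#' naive all-non-virus classifier on 3% prevalence scores 0.97 overall
#' precision yet zero virus recall. Undefined precision (no predictions for
#' a class) is reported as 0 with `precision_defined = FALSE`.
#'
#' @inheritParams roc_curve
#' @param threshold Classification threshold in `[0, 1]` (default 0.5).
#' @return A tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`, `precision_defined`.
#' @export
classify_at_threshold <- function(scores, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  y <- .binary_labels(labels)
  stopifnot(length(scores) == length(y))
  pred <- as.integer(scores >= threshold)
  one_class <- function(cls) {
    yp <- as.integer(pred == cls)
    yt <- as.integer(y == cls)
    tp <- sum(yp & yt)
    precision_defined <- sum(yp) > 0L
    precision <- if (precision_defined) tp / sum(yp) else 0
    recall <- if (sum(yt) > 0L) tp / sum(yt) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble(
      class = if (cls == 1L) "virus" else "non_virus",
      precision = precision, recall = recall, f1 = f1,
      support = sum(yt), precision_defined = precision_defined
    )
  }
  bind_rows(one_class(1L), one_class(0L))
}

#' Precision-recall trade-off for the virus class across thresholds
#'
#' Raising the classification threshold trades virus-class recall for
#' precision; this table supports choosing a high-precision operating point
#' for candidate-virus triage. Micro rows pool all folds; macro rows average
#' per-fold precision/recall with equal weight (folds with no true virus
#' samples are excluded from the macro recall mean, and undefined per-fold
#' precisions count as 0).
#'
#' @param folds Fold-result tibble (see [micro_average()]).
#' @param thresholds Numeric grid of thresholds in `[0, 1]`.
#' @return A tibble with columns `threshold`, `micro_precision`,
#'   `micro_recall`, `macro_precision`, `macro_recall`.
#' @export
precision_recall_tradeoff <- function(folds, thresholds = seq(0, 1, by = 0.01)) {
  folds <- .check_folds(folds)
  pooled_scores <- unlist(folds$scores)
  pooled_labels <- unlist(map(folds$labels, .binary_labels))
  fold_y <- map(folds$labels, .binary_labels)
  has_virus <- map_int(fold_y, sum) > 0L
  rows <- map(thresholds, function(t) {
    micro <- classify_at_threshold(pooled_scores, pooled_labels, t)
    micro_v <- micro[micro$class == "virus", ]
    per_fold <- map2(folds$scores, fold_y, function(s, y) {
      m <- classify_at_threshold(s, y, t)
      m[m$class == "virus", ]
    })
    tibble(
      threshold = t,
      micro_precision = micro_v$precision,
      micro_recall = micro_v$recall,
      macro_precision = mean(map_dbl(per_fold, "precision")),
      macro_recall = mean(map_dbl(per_fold[has_virus], "recall"))
    )
  })
  list_rbind(rows)
}
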