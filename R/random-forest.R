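#' Random-forest configuration
#'
#' Defaults are the best-performing configuration for the metagenomic
#' classification task: 5000 trees, balanced class weights, and no up- or
#' down-sampling.
#'
#' @param n_trees Number of trees (default 5000).
#' @param class_weight `"balanced"` (classes reweighted inversely to their
#'   frequency, `w_c = N / (2 * N_c)`) or `"none"`.
#' @param sampling `"none"`, `"upsample"` (minority class resampled with
#'   replacement up to the majority size) or `"downsample"` (majority class
#'   subsampled down to the minority size).
#' @param seed Integer seed; training is deterministic given (data, config,
#'   seed).
#' @param num_threads Threads used by the forest backend (default 1, which
#'   also guarantees reproducibility).
#' @return A list of class `viroscu_rf_config`.
#' @export
rf_config <- function(n_trees = 5000L, class_weight = c("balanced", "none"),
                      sampling = c("none", "upsample", "downsample"),
                      seed = 1L, num_threads = 1L) {
  structure(
    list(
      n_trees = .assert_scalar_int(n_trees, "n_trees"),
      class_weight = match.arg(class_weight),
      sampling = match.arg(sampling),
      seed = as.integer(seed),
      num_threads = .assert_scalar_int(num_threads, "num_threads")
    ),
    class = "viroscu_rf_config"
  )
}

# Pull (X, y) out of a feature tibble or a bare matrix + label vector.
.design_matrix <- function(features, labels = NULL) {
  if (is.data.frame(features) && all(rscu_codon_order() %in% names(features))) {
    X <- .feature_matrix(features)
    if (is.null(labels) && "label" %in% names(features)) labels <- features$label
  } else {
    X <- as.matrix(features)
  }
  if (ncol(X) != 59L) {
    abort(sprintf("expected 59 RSCU feature columns, got %d", ncol(X)))
  }
  if (is.null(labels)) abort("labels are required (column `label` or `labels` argument)")
  if (!.is_binary_labels(labels)) {
    abort("labels must be 'virus' or 'non_virus'")
  }
  if (anyNA(X)) abort("feature matrix contains missing values")
  list(X = X, y = .label_factor(labels))
}

.resample_rows <- function(X, y, sampling, seed) {
  if (sampling == "none") {
    return(list(X = X, y = y))
  }
  .with_seed(seed, {
    n_by_class <- table(y)
    idx <- switch(sampling,
      upsample = {
        target <- max(n_by_class)
        unlist(lapply(levels(y), function(cl) {
          rows <- which(y == cl)
          if (length(rows) < target) c(rows, sample(rows, target - length(rows), replace = TRUE)) else rows
        }))
      },
      downsample = {
        target <- min(n_by_class)
        unlist(lapply(levels(y), function(cl) {
          rows <- which(y == cl)
          if (length(rows) > target) sample(rows, target) else rows
        }))
      }
    )
    list(X = X[idx, , drop = FALSE], y = y[idx])
  })
}

#' Train the random-forest virus classifier
#'
#' Fits an ensemble of classification trees on 59-dimensional RSCU feature
#' rows, each tree on a bootstrap sample with a random feature subset
#' considered at every split, and predicts the probability that a strand
#' sample is viral. Raw RSCU values are consumed directly (tree splits are
#' invariant to monotone feature scaling).
#'
#' @param features Feature tibble from [extract_features()] (a `label` column
#'   supplies the response) or a numeric matrix with the 59 canonical columns.
#' @param labels Optional character vector of `virus`/`non_virus` labels,
#'   required when `features` carries no `label` column.
#' @param config A [rf_config()].
#' @return A fitted model of class `viroscu_rf` (and `viroscu_model`).
#' @seealso [predict_proba()], [gini_importance()]
#' @export
train_random_forest <- function(features, labels = NULL, config = rf_config()) {
  d <- .design_matrix(features, labels)
  if (nlevels(droplevels(d$y)) < 2L) {
    abort("training labels contain a single class; both virus and non_virus are required")
  }
  d2 <- .resample_rows(d$X, d$y, config$sampling, .derive_seed(config$seed, 17L))
  class_weights <- if (config$class_weight == "balanced") {
    n_by_class <- table(d2$y)
    as.numeric(length(d2$y) / (2 * n_by_class[levels(d2$y)]))
  } else {
    c(1, 1)
  }
  fit <- ranger::ranger(
    x = d2$X, y = d2$y,
    num.trees = config$n_trees,
    probability = TRUE,
    class.weights = class_weights,
    seed = config$seed,
    num.threads = config$num_threads,
    importance = "impurity"
  )
  structure(
    list(
      kind = "random_forest",
      config = config,
      fit = fit,
      fingerprint = rscu_codon_order(),
      n_train = length(d$y)
    ),
    class = c("viroscu_rf", "viroscu_model")
  )
}

#' Predict the probability that samples are viral
#'
#' @param model A fitted `viroscu_rf` or `viroscu_nn` model.
#' @param features Feature tibble or numeric matrix whose 59 feature columns
#'   match the model's feature-order fingerprint.
#' @return Numeric vector of `p(virus)` in `[0, 1]`, one per row (length 0 for
#'   zero rows).
#' @export
predict_proba <- function(model, features) {
  UseMethod("predict_proba")
}

.fingerprint_matrix <- function(model, features) {
  if (is.data.frame(features)) {
    missing_cols <- setdiff(model$fingerprint, names(features))
    if (length(missing_cols) > 0L) {
      abort(sprintf("feature columns do not match the model fingerprint (missing %s)", missing_cols[1]))
    }
    X <- as.matrix(features[, model$fingerprint])
  } else {
    X <- as.matrix(features)
    if (is.null(colnames(X))) {
      if (ncol(X) != length(model$fingerprint)) {
        abort("feature matrix width does not match the model fingerprint")
      }
      colnames(X) <- model$fingerprint
    } else if (!identical(colnames(X), model$fingerprint)) {
      abort("feature column order does not match the model fingerprint")
    }
  }
  X
}

#' @export
predict_proba.viroscu_rf <- function(model, features) {
  X <- .fingerprint_matrix(model, features)
  if (nrow(X) == 0L) {
    return(numeric(0))
  }
  pred <- predict(model$fit, data = X, num.threads = model$config$num_threads)
  unname(pred$predictions[, "virus"])
}

#' @export
print.viroscu_rf <- function(x, ...) {
  cat(sprintf(
    "<viroscu random forest: %d trees, class_weight=%s, sampling=%s, n_train=%d>\n",
    x$config$n_trees, x$config$class_weight, x$config$sampling, x$n_train
  ))
  invisible(x)
}

#' @export
glance.viroscu_rf <- function(x, ...) {
  tibble(
    kind = "random_forest",
    n_trees = x$config$n_trees,
    class_weight = x$config$class_weight,
    sampling = x$config$sampling,
    n_train = x$n_train,
    oob_error = x$fit$prediction.error
  )
}
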