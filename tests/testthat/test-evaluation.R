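# Splitters, ROC/AUROC, micro/macro averaging, threshold metrics.

fold_tbl <- function(...) {
  folds <- list(...)
  tibble::tibble(
    fold = names(folds),
    scores = lapply(folds, `[[`, "scores"),
    labels = lapply(folds, `[[`, "labels")
  )
}

test_that("loeo_split partitions samples by experiment", {
  f <- separable_features(n = 95L)
  folds <- loeo_split(f)
  expect_equal(nrow(folds), length(unique(f$experiment_id)))
  test_idx <- sort(unlist(folds$test))
  expect_equal(test_idx, seq_len(nrow(f)))
  for (i in seq_len(nrow(folds))) {
    expect_equal(sort(c(folds$train[[i]], folds$test[[i]])), seq_len(nrow(f)))
    expect_equal(unique(f$experiment_id[folds$test[[i]]]), folds$fold[i])
  }
  expect_error(loeo_split(dplyr::mutate(f, experiment_id = "only")), "at least 2")
})

test_that("kfold_split stratifies and keeps contig strand pairs together", {
  d <- generate_dataset(n_experiments = 2, contigs_per_experiment = 60, virus_prevalence = 0.2, seed = 33)
  f <- extract_features(d, quiet = TRUE)
  folds <- kfold_split(f, k = 5L, seed = 2L)
  expect_equal(sort(unname(unlist(folds$test))), seq_len(nrow(f)))
  sizes <- lengths(folds$test)
  expect_lte(max(sizes) - min(sizes), 4L) # near-equal up to contig grouping
  global_virus <- sum(f$label == "virus")
  for (i in 1:5) {
    test_rows <- f[folds$test[[i]], ]
    # strands of one contig never straddle the split
    expect_length(intersect(test_rows$contig_id, f$contig_id[folds$train[[i]]]), 0L)
    expect_lte(abs(sum(test_rows$label == "virus") - global_virus / 5), 2.5)
  }
  expect_error(kfold_split(f[1:4, ], k = 10L), "exceeds")
})

test_that("roc_curve handles perfect, inverted and degenerate scorers", {
  labels <- c(1, 0, 1, 0, 0)
  expect_equal(auroc(labels, labels), 1.0)
  expect_equal(auroc(1 - labels, labels), 0.0)
  expect_error(roc_curve(runif(4), rep(1, 4)), "both classes")
})

test_that("AUROC equals the pairwise-concordance oracle, ties counted half", {
  withr::with_seed(55, {
    for (i in 1:40) {
      n <- sample(20:200, 1L)
      scores <- round(runif(n), sample(c(1L, 2L, 3L), 1L)) # force ties
      labels <- rbinom(n, 1L, 0.3)
      if (sum(labels) == 0L || sum(labels) == n) next
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("micro equals roc_curve on one fold and matches the oracle on pooled sets", {
  withr::with_seed(60, {
    scores <- runif(80)
    labels <- rbinom(80, 1, 0.4)
    one <- fold_tbl(a = list(scores = scores, labels = labels))
    expect_equal(micro_average(one)$auroc, auroc(scores, labels))
    two <- fold_tbl(
      a = list(scores = scores[1:40], labels = labels[1:40]),
      b = list(scores = scores[41:80], labels = labels[41:80])
    )
    expect_equal(micro_average(two)$auroc, oracle_auroc(scores, labels))
  })
})

test_that("micro and macro coincide for identical folds and macro averages per-fold areas", {
  withr::with_seed(61, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.3)
    twin <- fold_tbl(
      a = list(scores = scores, labels = labels),
      b = list(scores = scores, labels = labels)
    )
    expect_equal(micro_average(twin)$auroc, macro_average(twin)$auroc, tolerance = 1e-12)
    # macro AUROC is the arithmetic mean of two unequal per-fold areas
    mk <- function(pos_ranks) {
      s <- seq(0.1, 1, length.out = 10L)
      y <- rep(0L, 10L)
      y[pos_ranks] <- 1L
      list(scores = s, labels = y)
    }
    pair <- fold_tbl(lo = mk(c(5L, 9L)), hi = mk(c(7L, 10L)))
    per <- vapply(seq_len(2), function(i) auroc(pair$scores[[i]], pair$labels[[i]]), numeric(1))
    expect_equal(macro_average(pair)$auroc, mean(per), tolerance = 1e-12)
    # fold order is irrelevant
    expect_equal(macro_average(pair[2:1, ])$auroc, macro_average(pair)$auroc)
  })
})

test_that("macro averaging drops single-class folds with a warning", {
  withr::with_seed(62, {
    good <- list(scores = runif(30), labels = rbinom(30, 1, 0.5))
    empty <- list(scores = runif(10), labels = rep(0L, 10))
    folds <- fold_tbl(good = good, empty = empty)
    expect_warning(out <- macro_average(folds), "dropping")
    expect_equal(out$dropped_folds, "empty")
    expect_equal(out$auroc, auroc(good$scores, good$labels))
  })
})

test_that("per-class metrics reproduce confusion-table arithmetic", {
  # 10 samples, 2 virus; one true virus flagged, no false positives
  labels <- c(rep("virus", 2L), rep("non_virus", 8L))
  scores <- c(0.9, 0.1, rep(0.1, 8L))
  m <- classify_at_threshold(scores, labels, 0.5)
  virus <- m[m$class == "virus", ]
  expect_equal(virus$precision, 1.0)
  expect_equal(virus$recall, 0.5)
  # all-negative predictions at 97% non-virus prevalence
  labels2 <- c(rep("virus", 3L), rep("non_virus", 97L))
  m2 <- classify_at_threshold(rep(0.1, 100L), labels2, 0.5)
  nonvirus <- m2[m2$class == "non_virus", ]
  expect_equal(nonvirus$precision, 0.97)
  expect_equal(nonvirus$recall, 1.0)
  virus2 <- m2[m2$class == "virus", ]
  expect_false(virus2$precision_defined)
  expect_equal(virus2$precision, 0)
  # threshold 0 predicts everything viral
  m3 <- classify_at_threshold(runif(20), rbinom(20, 1, 0.5), 0)
  expect_equal(m3$recall[m3$class == "virus"], 1.0)
})

test_that("the precision-recall trade-off is consistent and recall-monotone", {
  withr::with_seed(63, {
    folds <- fold_tbl(
      a = list(scores = runif(50), labels = rbinom(50, 1, 0.2)),
      b = list(scores = runif(70), labels = rbinom(70, 1, 0.1))
    )
    grid <- seq(0, 1, by = 0.05)
    tr <- precision_recall_tradeoff(folds, grid)
    expect_equal(tr$micro_recall[tr$threshold == 0], 1.0)
    expect_equal(tr$micro_recall[tr$threshold == 1], 0.0)
    expect_true(all(diff(tr$micro_recall) <= 1e-12))
    expect_true(all(diff(tr$macro_recall) <= 1e-12))
    # micro row equals classify_at_threshold on the pooled set
    pooled_s <- unlist(folds$scores)
    pooled_y <- unlist(folds$labels)
    for (t in c(0.25, 0.5, 0.75)) {
      m <- classify_at_threshold(pooled_s, pooled_y, t)
      expect_equal(tr$micro_precision[abs(tr$threshold - t) < 1e-9], m$precision[m$class == "virus"])
      expect_equal(tr$micro_recall[abs(tr$threshold - t) < 1e-9], m$recall[m$class == "virus"])
    }
  })
})

test_that("roc_curve agrees with an independent ROC implementation", {
  withr::with_seed(64, {
    scores <- runif(150)
    labels <- rbinom(150, 1, 0.3)
    expect_equal(
      auroc(scores, labels),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<")))
    )
  })
})
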