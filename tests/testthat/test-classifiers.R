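# Random forest and neural net: contracts, determinism, sanity on separable
# data, class-weight behaviour.

small_nn <- function(seed = 1L, epochs = 10L, ...) {
  nn_config(
    hidden_layers = c(32L, 32L), epochs = epochs,
    initial_learning_rate = 1e-2, seed = seed, ...
  )
}

test_that("random forest separates a linearly separable set and is seed-deterministic", {
  f <- separable_features(n = 200L, seed = 3L)
  m1 <- train_random_forest(f, config = rf_config(n_trees = 100L, seed = 9L))
  m2 <- train_random_forest(f, config = rf_config(n_trees = 100L, seed = 9L))
  p1 <- predict_proba(m1, f)
  p2 <- predict_proba(m2, f)
  expect_identical(p1, p2)
  expect_gte(auroc(p1, f$label), 0.99)
  expect_gt(mean(p1[f$label == "virus"]), mean(p1[f$label == "non_virus"]))
})

test_that("degenerate classifier inputs are rejected", {
  f <- separable_features(n = 50L)
  f$label <- "virus"
  expect_error(train_random_forest(f, config = rf_config(n_trees = 10L)), "single class")
  expect_error(train_neural_net(f, config = small_nn()), "single class")
  bad <- separable_features(n = 30L)[, 1:30]
  expect_error(
    train_random_forest(bad, labels = rep(c("virus", "non_virus"), 15L)),
    "59"
  )
})

test_that("the neural net learns a separable set, stays in [0,1], and is deterministic", {
  f <- separable_features(n = 300L, seed = 5L)
  m1 <- train_neural_net(f, config = small_nn(seed = 4L))
  m2 <- train_neural_net(f, config = small_nn(seed = 4L))
  p1 <- predict_proba(m1, f)
  expect_identical(p1, predict_proba(m2, f))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_true(all(is.finite(p1)))
  expect_gte(auroc(p1, f$label), 0.95)
  expect_true(all(is.finite(m1$loss_by_epoch)))
  expect_lt(tail(m1$loss_by_epoch, 1L), m1$loss_by_epoch[1L])
})

test_that("class_weight_power 0 gives uniform weights; balanced formula at power 1", {
  f <- separable_features(n = 120L, prevalence = 0.25, seed = 6L)
  m0 <- train_neural_net(f, config = small_nn(epochs = 1L, class_weight_power = 0))
  expect_equal(unname(m0$class_weights), c(1, 1))
  m1 <- train_neural_net(f, config = small_nn(epochs = 1L, class_weight_power = 1))
  n <- nrow(f)
  n_virus <- sum(f$label == "virus")
  expect_equal(unname(m1$class_weights["virus"]), n / (2 * n_virus))
  expect_equal(unname(m1$class_weights["non_virus"]), n / (2 * (n - n_virus)))
})

test_that("predict_proba honours the feature fingerprint and empty input", {
  f <- separable_features(n = 60L)
  m <- train_random_forest(f, config = rf_config(n_trees = 20L))
  expect_length(predict_proba(m, f[0, ]), 0L)
  shuffled <- as.matrix(f[, rev(rscu_codon_order())])
  expect_error(predict_proba(m, shuffled), "fingerprint")
})

test_that("rf probabilities agree qualitatively with an independent forest implementation", {
  f <- separable_features(n = 150L, seed = 8L)
  m <- train_random_forest(f, config = rf_config(n_trees = 200L, class_weight = "none"))
  p <- predict_proba(m, f)
  ref <- randomForest::randomForest(
    x = as.matrix(f[, rscu_codon_order()]),
    y = factor(f$label, levels = c("non_virus", "virus"))
  )
  p_ref <- predict(ref, as.matrix(f[, rscu_codon_order()]), type = "prob")[, "virus"]
  expect_gt(cor(p, p_ref), 0.9)
})

test_that("permuted labels yield chance-level cross-validated AUROC", {
  aucs <- vapply(1:5, function(seed) {
    f <- separable_features(n = 240L, shift = 0, seed = 100L + seed)
    cv <- crossvalidate(
      f,
      folds = kfold_split(f, k = 4L, seed = seed),
      config = rf_config(n_trees = 100L, seed = seed)
    )
    micro_average(cv)$auroc
  }, numeric(1))
  expect_gte(sum(aucs >= 0.4 & aucs <= 0.6), 4L)
  expect_true(all(aucs >= 0.3 & aucs <= 0.7))
})

test_that("balanced class weights do not reduce rare-class recall", {
  recall_at_half <- function(scores, labels) {
    m <- classify_at_threshold(scores, labels)
    m$recall[m$class == "virus"]
  }
  diffs <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      f <- separable_features(n = 400L, shift = 0.9, prevalence = 0.03, seed = 200L + seed)
      holdout <- separable_features(n = 400L, shift = 0.9, prevalence = 0.03, seed = 300L + seed)
      mb <- train_random_forest(f, config = rf_config(n_trees = 100L, class_weight = "balanced", seed = seed))
      mu <- train_random_forest(f, config = rf_config(n_trees = 100L, class_weight = "none", seed = seed))
      recall_at_half(predict_proba(mb, holdout), holdout$label) -
        recall_at_half(predict_proba(mu, holdout), holdout$label)
    })
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("up/down-sampling run and remain deterministic", {
  f <- separable_features(n = 120L, prevalence = 0.2, seed = 10L)
  for (s in c("upsample", "downsample")) {
    m1 <- train_random_forest(f, config = rf_config(n_trees = 30L, sampling = s, seed = 2L))
    m2 <- train_random_forest(f, config = rf_config(n_trees = 30L, sampling = s, seed = 2L))
    expect_identical(predict_proba(m1, f), predict_proba(m2, f))
  }
})
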