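#' Feed-forward neural-network configuration
#'
#' Defaults are the best-performing network for the metagenomic task: two
#' fully-connected hidden layers of 1024 ReLU units, dropout 0.25,
#' class-weight power 0.25, trained for 10 epochs with Adam at an initial
#' learning rate of 1e-4 multiplied by 0.95 after each epoch.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability applied after each hidden layer
#'   during training, in `[0, 1)`.
#' @param class_weight_power Exponent `p` of the per-class training weight
#'   `w_c = (N / (2 * N_c))^p`; `p = 0` gives uniform weights, `p = 1` fully
#'   balanced weights.
#' @param epochs Number of training epochs.
#' @param initial_learning_rate Adam learning rate in epoch 1.
#' @param lr_decay_per_epoch Multiplier applied to the learning rate after
#'   each epoch.
#' @param batch_size Minibatch size for the binary cross-entropy loss.
#' @param seed Integer seed; training is deterministic given (data, config,
#'   seed).
#' @return A list of class `viroscu_nn_config`.
#' @export
nn_config <- function(hidden_layers = c(1024L, 1024L), dropout_rate = 0.25,
                      class_weight_power = 0.25, epochs = 10L,
                      initial_learning_rate = 1e-4, lr_decay_per_epoch = 0.95,
                      batch_size = 128L, seed = 1L) {
  stopifnot(
    length(hidden_layers) >= 1L, all(hidden_layers >= 1L),
    dropout_rate >= 0, dropout_rate < 1,
    class_weight_power >= 0,
    initial_learning_rate > 0, lr_decay_per_epoch > 0
  )
  structure(
    list(
      hidden_layers = as.integer(hidden_layers),
      activation = "relu",
      dropout_rate = dropout_rate,
      class_weight_power = class_weight_power,
      epochs = .assert_scalar_int(epochs, "epochs"),
      initial_learning_rate = initial_learning_rate,
      lr_decay_per_epoch = lr_decay_per_epoch,
      batch_size = .assert_scalar_int(batch_size, "batch_size"),
      seed = as.integer(seed)
    ),
    class = "viroscu_nn_config"
  )
}

# He-style initialization for ReLU layers
.init_mlp <- function(sizes) {
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(
      rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
      nrow = sizes[l], ncol = sizes[l + 1L]
    )
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; when `masks` is non-NULL, inverted dropout is applied after
# each hidden activation. Returns activations needed for backprop.
.mlp_forward <- function(params, X, masks = NULL) {
  n_hidden <- length(params$W) - 1L
  A <- vector("list", n_hidden + 1L)
  Z <- vector("list", n_hidden + 1L)
  a <- X
  for (l in seq_len(n_hidden)) {
    z <- sweep(a %*% params$W[[l]], 2L, params$b[[l]], "+")
    h <- pmax(z, 0)
    if (!is.null(masks)) h <- h * masks[[l]]
    Z[[l]] <- z
    A[[l]] <- h
    a <- h
  }
  z_out <- drop(a %*% params$W[[n_hidden + 1L]]) + params$b[[n_hidden + 1L]]
  list(Z = Z, A = A, z_out = z_out, p = .sigmoid(z_out))
}

# One Adam update step over all parameter matrices.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W", "b")) {
    for (l in seq_along(params[[nm]])) {
      g <- grads[[nm]][[l]]
      state$m[[nm]][[l]] <- beta1 * state$m[[nm]][[l]] + (1 - beta1) * g
      state$v[[nm]][[l]] <- beta2 * state$v[[nm]][[l]] + (1 - beta2) * g^2
      m_hat <- state$m[[nm]][[l]] / (1 - beta1^state$t)
      v_hat <- state$v[[nm]][[l]] / (1 - beta2^state$t)
      params[[nm]][[l]] <- params[[nm]][[l]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train the feed-forward neural-network virus classifier
#'
#' A fully-connected network (ReLU hidden layers, sigmoid output) trained with
#' minibatch Adam on a class-weighted binary cross-entropy loss. Features are
#' standardized internally (per-feature z-score fitted on the training data
#' only); the per-class weights `w_c = (N / (2 * N_c))^p` counteract class
#' imbalance with tunable strength `p`, and the learning rate follows
#' `lr_e = initial * decay^(e - 1)` across epochs. The implementation is the
#' package's own compact dense-network engine in base R matrix algebra, so the
#' fitted model is a plain R object.
#'
#' @inheritParams train_random_forest
#' @param config A [nn_config()].
#' @return A fitted model of class `viroscu_nn` (and `viroscu_model`) with the
#'   per-epoch training loss recorded in `$loss_by_epoch`.
#' @export
train_neural_net <- function(features, labels = NULL, config = nn_config()) {
  d <- .design_matrix(features, labels)
  if (nlevels(droplevels(d$y)) < 2L) {
    abort("training labels contain a single class; both virus and non_virus are required")
  }
  X <- d$X
  y <- as.numeric(d$y == "virus")
  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")

  n <- nrow(Xs)
  n_virus <- sum(y)
  w_class <- c(
    non_virus = (n / (2 * (n - n_virus)))^config$class_weight_power,
    virus = (n / (2 * n_virus))^config$class_weight_power
  )
  w_sample <- ifelse(y == 1, w_class[["virus"]], w_class[["non_virus"]])

  sizes <- c(ncol(Xs), config$hidden_layers, 1L)
  loss_by_epoch <- numeric(config$epochs)

  params <- .with_seed(config$seed, {
    params <- .init_mlp(sizes)
    zero_like <- function(p) lapply(p, function(x) x * 0)
    state <- list(
      t = 0L,
      m = list(W = zero_like(params$W), b = zero_like(params$b)),
      v = list(W = zero_like(params$W), b = zero_like(params$b))
    )
    n_hidden <- length(config$hidden_layers)
    for (epoch in seq_len(config$epochs)) {
      lr <- config$initial_learning_rate * config$lr_decay_per_epoch^(epoch - 1L)
      order_ <- sample.int(n)
      batch_starts <- seq.int(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (bs in batch_starts) {
        idx <- order_[bs:min(bs + config$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        yb <- y[idx]
        wb <- w_sample[idx]
        nb <- length(idx)
        masks <- NULL
        if (config$dropout_rate > 0) {
          masks <- lapply(config$hidden_layers, function(width) {
            matrix(
              (runif(nb * width) >= config$dropout_rate) / (1 - config$dropout_rate),
              nrow = nb, ncol = width
            )
          })
        }
        fwd <- .mlp_forward(params, Xb, masks)
        p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
        loss <- mean(wb * -(yb * log(p) + (1 - yb) * log(1 - p)))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss in epoch %d", epoch))
        }
        epoch_loss <- epoch_loss + loss * nb

        # backprop: d(loss)/d(z_out) for weighted BCE with sigmoid output
        dZ <- matrix(wb * (p - yb) / nb, ncol = 1L)
        gW <- vector("list", n_hidden + 1L)
        gb <- vector("list", n_hidden + 1L)
        a_prev <- if (n_hidden > 0L) fwd$A[[n_hidden]] else Xb
        gW[[n_hidden + 1L]] <- crossprod(a_prev, dZ)
        gb[[n_hidden + 1L]] <- colSums(dZ)
        dA <- dZ %*% t(params$W[[n_hidden + 1L]])
        for (l in rev(seq_len(n_hidden))) {
          if (!is.null(masks)) dA <- dA * masks[[l]]
          dZl <- dA * (fwd$Z[[l]] > 0)
          a_prev <- if (l > 1L) fwd$A[[l - 1L]] else Xb
          gW[[l]] <- crossprod(a_prev, dZl)
          gb[[l]] <- colSums(dZl)
          if (l > 1L) dA <- dZl %*% t(params$W[[l]])
        }
        upd <- .adam_step(params, list(W = gW, b = gb), state, lr)
        params <- upd$params
        state <- upd$state
      }
      loss_by_epoch[epoch] <- epoch_loss / n
    }
    params
  })

  structure(
    list(
      kind = "neural_net",
      config = config,
      params = params,
      center = center,
      scale = scale_,
      class_weights = w_class,
      loss_by_epoch = loss_by_epoch,
      fingerprint = rscu_codon_order(),
      n_train = n
    ),
    class = c("viroscu_nn", "viroscu_model")
  )
}

#' @export
predict_proba.viroscu_nn <- function(model, features) {
  X <- .fingerprint_matrix(model, features)
  if (nrow(X) == 0L) {
    return(numeric(0))
  }
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  unname(.mlp_forward(model$params, Xs)$p)
}

#' @export
print.viroscu_nn <- function(x, ...) {
  cat(sprintf(
    "<viroscu neural net: layers [%s], dropout %.2f, class_weight_power %.2f, %d epochs, n_train=%d>\n",
    paste(x$config$hidden_layers, collapse = ", "),
    x$config$dropout_rate, x$config$class_weight_power, x$config$epochs, x$n_train
  ))
  invisible(x)
}

#' @export
glance.viroscu_nn <- function(x, ...) {
  tibble(
    kind = "neural_net",
    hidden_layers = paste(x$config$hidden_layers, collapse = "x"),
    dropout_rate = x$config$dropout_rate,
    class_weight_power = x$config$class_weight_power,
    epochs = x$config$epochs,
    final_loss = tail(x$loss_by_epoch, 1L),
    n_train = x$n_train
  )
}
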