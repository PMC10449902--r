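#' Specification of the co-elution classifier
#'
#' Architecture and training hyperparameters of the fully connected
#' network that scores candidate pairs: an input layer the size of the
#' feature vector (147 for 72 fractions), a 100-unit and a 72-unit hidden
#' layer (ReLU), dropout 0.2 after the 100-unit layer, and a single
#' sigmoid output unit. Trained with Adam (learning rate 0.001) on binary
#' cross-entropy for up to 100 epochs with early stopping (patience 20) on
#' a validation split.
#'
#' @param layer_sizes Integer vector: input size followed by hidden layer
#'   sizes (default `c(147, 100, 72)`); the sigmoid output unit is implied.
#' @param dropout_rate Dropout rate after the first hidden layer
#'   (default 0.2).
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Maximum training epochs (default 100).
#' @param early_stopping_patience Epochs without validation-loss
#'   improvement tolerated before stopping (default 20).
#' @param validation_split Share of examples held out for early stopping
#'   (default 0.2, stratified by label).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling initialization, the validation
#'   split, shuffling and dropout masks.
#' @return A `cf_classifier_spec` list.
#' @export
classifier_spec <- function(layer_sizes = c(147L, 100L, 72L),
                            dropout_rate = 0.2,
                            learning_rate = 0.001,
                            max_epochs = 100L,
                            early_stopping_patience = 20L,
                            validation_split = 0.2,
                            batch_size = 32L,
                            seed = 1L) {
  spec <- list(layer_sizes = as.integer(layer_sizes),
               dropout_rate = dropout_rate, learning_rate = learning_rate,
               max_epochs = as.integer(max_epochs),
               early_stopping_patience = as.integer(early_stopping_patience),
               validation_split = validation_split,
               batch_size = as.integer(batch_size), seed = as.integer(seed))
  stopifnot(length(spec$layer_sizes) >= 2, all(spec$layer_sizes > 0),
            spec$dropout_rate >= 0, spec$dropout_rate < 1,
            spec$validation_split >= 0, spec$validation_split < 1)
  class(spec) <- "cf_classifier_spec"
  spec
}

#' Build an untrained co-elution classifier
#'
#' Allocates the network weights with Glorot-uniform initialization,
#' deterministic under the spec's seed.
#'
#' @param spec A [classifier_spec()].
#' @return A `cf_classifier` object (untrained).
#' @export
build_classifier <- function(spec = classifier_spec()) {
  stopifnot(inherits(spec, "cf_classifier_spec"))
  set.seed(spec$seed)
  dims <- c(spec$layer_sizes, 1L)
  weights <- vector("list", length(dims) - 1)
  for (l in seq_along(weights)) {
    fan_in <- dims[l]; fan_out <- dims[l + 1]
    limit <- sqrt(6 / (fan_in + fan_out))
    weights[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -limit, limit),
                 fan_in, fan_out),
      b = rep(0, fan_out)
    )
  }
  structure(list(spec = spec, weights = weights, trained = FALSE,
                 history = NULL), class = "cf_classifier")
}

#' Number of trainable parameters of a classifier
#'
#' @param model A `cf_classifier`.
#' @return Integer count of weights plus biases (22,145 for the default
#'   147-100-72-1 architecture).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, function(l) length(l$W) + length(l$b), 0))
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; returns activations for backprop. Dropout (inverted
# scaling) is applied after the first hidden layer only when a mask is
# supplied, i.e. during training.
nn_forward <- function(weights, X, dropout_mask = NULL) {
  L <- length(weights)
  a <- vector("list", L + 1)
  a[[1]] <- X
  z <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    if (l < L) {
      a[[l + 1]] <- relu(z[[l]])
      if (l == 1 && !is.null(dropout_mask)) {
        a[[l + 1]] <- a[[l + 1]] * dropout_mask
      }
    } else {
      a[[l + 1]] <- sigmoid(z[[l]])
    }
  }
  list(a = a, z = z)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gradients of mean BCE w.r.t. every weight and bias
nn_gradients <- function(weights, fwd, y, dropout_mask = NULL) {
  L <- length(weights)
  n <- length(y)
  grads <- vector("list", L)
  p <- fwd$a[[L + 1]]
  delta <- (p - matrix(y, ncol = 1)) / n  # sigmoid + BCE simplification
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fwd$a[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(weights[[l]]$W)) * (fwd$z[[l - 1]] > 0)
      if (l - 1 == 1 && !is.null(dropout_mask)) delta <- delta * dropout_mask
    }
  }
  grads
}

#' Train the co-elution classifier
#'
#' Minibatch Adam on binary cross-entropy, with a stratified validation
#' split for early stopping: training halts when the validation loss has
#' not improved for `early_stopping_patience` consecutive epochs (or at
#' `max_epochs`), and the weights from the best validation epoch are
#' restored. Fully deterministic under the spec seed.
#'
#' @param model An untrained (or previously trained) `cf_classifier`.
#' @param features Numeric feature matrix (rows = examples) or a tibble
#'   with a `features` list-column from [featurize()].
#' @param labels 0/1 vector, one per example.
#' @param spec Optional [classifier_spec()] overriding the model's.
#' @param validation_idx Optional integer indices of examples to use as
#'   the validation set instead of the random stratified split. Use this
#'   to hold out whole datasets: with positional per-fraction features, a
#'   random split shares elution layouts between training and validation
#'   and cannot detect layout memorization.
#' @return The trained `cf_classifier`, with a `history` tibble (epoch,
#'   training and validation loss) and a `report` list (epochs run, best
#'   epoch, final losses). Inspect with [tidy()] / [glance()].
#' @export
train_classifier <- function(model, features, labels, spec = NULL,
                             validation_idx = NULL) {
  stopifnot(inherits(model, "cf_classifier"))
  spec <- spec %||% model$spec
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  y <- as.numeric(labels)
  if (length(y) != nrow(X)) stop("labels do not match feature rows", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training needs at least one example of each class", call. = FALSE)
  }
  if (ncol(X) != spec$layer_sizes[1]) {
    stop("feature length ", ncol(X), " does not match classifier input ",
         spec$layer_sizes[1], call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("features must be finite", call. = FALSE)
  }

  # z-score the feature columns: the blocks live on very different scales
  # (correlations in [-1,1], peak shifts in fractions up to F), and Adam
  # converges poorly on mixed scales. The training statistics travel with
  # the model and are re-applied at prediction time.
  feat_mean <- colMeans(X)
  feat_sd <- apply(X, 2, stats::sd)
  feat_sd[feat_sd < 1e-8] <- 1
  X <- sweep(sweep(X, 2, feat_mean), 2, feat_sd, "/")
  model$scaling <- list(mean = feat_mean, sd = feat_sd)

  set.seed(spec$seed + 1L)
  # stratified validation split (unless explicit indices are given)
  val_idx <- integer(0)
  if (!is.null(validation_idx)) {
    val_idx <- as.integer(validation_idx)
    stopifnot(all(val_idx >= 1), all(val_idx <= length(y)))
  } else if (spec$validation_split > 0) {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      n_val <- max(1L, round(spec$validation_split * length(idx)))
      if (n_val >= length(idx)) n_val <- length(idx) - 1L
      if (n_val > 0) val_idx <- c(val_idx, sample(idx, n_val))
    }
  }
  tr_idx <- setdiff(seq_along(y), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  monitor_val <- length(val_idx) > 0

  weights <- model$weights
  # Adam state
  mstate <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L

  best_loss <- Inf
  best_weights <- weights
  best_epoch <- 0L
  wait <- 0L
  history <- vector("list", spec$max_epochs)
  epochs_run <- 0L

  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample(length(ytr))
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    for (batch in batches) {
      Xb <- Xtr[batch, , drop = FALSE]
      mask <- if (spec$dropout_rate > 0) {
        matrix(stats::rbinom(length(batch) * spec$layer_sizes[2], 1,
                             1 - spec$dropout_rate) / (1 - spec$dropout_rate),
               length(batch), spec$layer_sizes[2])
      } else NULL
      fwd <- nn_forward(weights, Xb, mask)
      grads <- nn_gradients(weights, fwd, ytr[batch], mask)
      t <- t + 1L
      for (l in seq_along(weights)) {
        for (par in c("W", "b")) {
          g <- grads[[l]][[par]]
          mstate[[l]][[par]] <- beta1 * mstate[[l]][[par]] + (1 - beta1) * g
          vstate[[l]][[par]] <- beta2 * vstate[[l]][[par]] + (1 - beta2) * g^2
          mhat <- mstate[[l]][[par]] / (1 - beta1^t)
          vhat <- vstate[[l]][[par]] / (1 - beta2^t)
          weights[[l]][[par]] <- weights[[l]][[par]] -
            spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    train_loss <- bce_loss(nn_forward(weights, Xtr)$a[[length(weights) + 1]],
                           ytr)
    val_loss <- if (monitor_val) {
      bce_loss(nn_forward(weights, Xval)$a[[length(weights) + 1]], yval)
    } else train_loss
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = train_loss,
                                       val_loss = val_loss)
    epochs_run <- epoch
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_weights <- weights
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= max(1L, spec$early_stopping_patience)) break
    }
  }

  model$weights <- best_weights
  model$trained <- TRUE
  model$spec <- spec
  model$history <- dplyr::bind_rows(history[seq_len(epochs_run)])
  model$report <- list(epochs_run = epochs_run, best_epoch = best_epoch,
                       best_val_loss = best_loss,
                       final_train_loss = model$history$train_loss[best_epoch],
                       n_train = length(tr_idx), n_validation = length(val_idx))
  model
}

#' Predict co-elution probabilities
#'
#' Forward pass of the trained network with dropout disabled; outputs are
#' strictly inside (0, 1).
#'
#' @param model A trained `cf_classifier`.
#' @param features Feature matrix, single feature vector, or tibble with a
#'   `features` list-column.
#' @return Numeric probability per example.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "cf_classifier"))
  X <- if (is.data.frame(features)) {
    feature_matrix(features)
  } else if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != model$spec$layer_sizes[1]) {
    stop("feature length ", ncol(X), " does not match classifier input ",
         model$spec$layer_sizes[1], call. = FALSE)
  }
  if (!is.null(model$scaling)) {
    X <- sweep(sweep(X, 2, model$scaling$mean), 2, model$scaling$sd, "/")
  }
  as.numeric(nn_forward(model$weights, X)$a[[length(model$weights) + 1]])
}

#' @export
print.cf_classifier <- function(x, ...) {
  cat("Co-elution classifier:",
      paste(c(x$spec$layer_sizes, 1), collapse = "-"),
      sprintf("(%d parameters, %s)\n", n_parameters(x),
              if (x$trained) "trained" else "untrained"))
  if (x$trained) {
    cat(sprintf("  epochs: %d (best %d), val loss %.4f\n",
                x$report$epochs_run, x$report$best_epoch,
                x$report$best_val_loss))
  }
  invisible(x)
}

#' Tidy the training history of a classifier
#'
#' @param x A trained `cf_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_loss`.
#' @exportS3Method generics::tidy
tidy.cf_classifier <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = double(),
                                val_loss = double())
}

#' One-row summary of a classifier fit
#'
#' @param x A trained `cf_classifier`.
#' @param ... Unused.
#' @return One-row tibble: parameter count, epochs run, best epoch, losses.
#' @exportS3Method generics::glance
glance.cf_classifier <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x),
    trained = x$trained,
    epochs_run = x$report$epochs_run %||% NA_integer_,
    best_epoch = x$report$best_epoch %||% NA_integer_,
    best_val_loss = x$report$best_val_loss %||% NA_real_,
    final_train_loss = x$report$final_train_loss %||% NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
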