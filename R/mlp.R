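## From-scratch multi-layer perceptron, trained by full-batch gradient
## descent on the mean-squared error of the 1 (healthy) / 2 (unhealthy)
## target encoding. The reference architecture is 15-30-20-1 with tansig
## (hyperbolic tangent) hidden layers and a linear output neuron; scores are
## thresholded at 1.5.

#' Initialize an MLP
#'
#' Weights are drawn uniformly in `+-1/sqrt(fan_in)`; biases start at zero.
#' Hidden layers use the tansig activation, the output layer is linear.
#'
#' @param layer_sizes Integer vector of layer widths, input first; the
#'   reference network is `c(15, 30, 20, 1)`.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return An `mlp_model`: `layer_sizes`, `weights` (list of matrices, layer
#'   `l` being `size_l x size_{l-1}`), `biases`, `activations`, a decision
#'   `threshold` of 1.5, and a `standardizer` slot filled in by [train_mlp()].
#' @export
init_mlp <- function(layer_sizes = c(15, 30, 20, 1), seed = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes needs at least an input and an output layer, all >= 1",
         call. = FALSE)
  }
  n_layers <- length(layer_sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  with_seed(seed, {
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      lim <- 1 / sqrt(fan_in)
      weights[[l]] <- matrix(stats::runif(layer_sizes[l + 1L] * fan_in,
                                          -lim, lim),
                             nrow = layer_sizes[l + 1L])
      biases[[l]] <- numeric(layer_sizes[l + 1L])
    }
  })
  structure(
    list(layer_sizes = layer_sizes, weights = weights, biases = biases,
         activations = c(rep("tansig", n_layers - 1L), "linear"),
         standardizer = NULL, threshold = 1.5),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model %s> %d parameters, activations: %s\n",
              paste(x$layer_sizes, collapse = "-"), n_params(x),
              paste(x$activations, collapse = "/")))
  if (!is.null(x$standardizer)) cat("  standardizer: fitted\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `mlp_model`.
#' @return Integer count of weights plus biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, integer(1))) +
    sum(vapply(model$biases, length, integer(1)))
}

.act <- function(z, tag) if (tag == "tansig") tanh(z) else z
.act_deriv <- function(z, tag) if (tag == "tansig") 1 - tanh(z)^2 else 1

#' Forward propagation
#'
#' Computes `a^l = sigma(W^l a^{l-1} + b^l)` layer by layer, returning every
#' activation and pre-activation (as needed by [backward_mlp()]).
#'
#' @param model An `mlp_model`.
#' @param x Input matrix, one column per sample (`size_input x n`), or a
#'   vector for a single sample. Inputs are used as given: standardize first
#'   for trained models (see [predict_mlp()]).
#' @return List with `a` (activations, `a[[1]]` the input) and `z`
#'   (pre-activations per layer).
#' @export
forward_mlp <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != model$layer_sizes[1L]) {
    stop("input has ", nrow(x), " features but the model expects ",
         model$layer_sizes[1L], call. = FALSE)
  }
  n_layers <- length(model$weights)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  a[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z[[l]] <- model$weights[[l]] %*% a[[l]] + model$biases[[l]]
    a[[l + 1L]] <- .act(z[[l]], model$activations[l])
  }
  list(a = a, z = z)
}

#' Mean squared error
#'
#' `(1/N) * sum((y - yhat)^2)` over all paired entries.
#'
#' @param y,yhat Numeric vectors or matrices of equal length.
#' @return Nonnegative scalar.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop("y and yhat must have equal positive length", call. = FALSE)
  }
  mean((as.numeric(y) - as.numeric(yhat))^2)
}

#' Backward propagation
#'
#' Gradient of the mean-squared error with respect to every weight and bias,
#' via the error recursion `delta^l = (W^{l+1})' delta^{l+1} * sigma'(z^l)`
#' (tansig derivative `1 - tanh(z)^2`).
#'
#' @param model An `mlp_model`.
#' @param cache The forward pass of [forward_mlp()] on the same model/input.
#' @param y Target matrix/vector matching the output layer (`size_out x n`).
#' @return List with `dW` and `db`, shaped like the model's weights/biases.
#' @export
backward_mlp <- function(model, cache, y) {
  stopifnot(inherits(model, "mlp_model"))
  n_layers <- length(model$weights)
  out <- cache$a[[n_layers + 1L]]
  if (is.vector(y)) y <- matrix(y, nrow = nrow(out))
  if (!all(dim(y) == dim(out))) {
    stop("target shape ", paste(dim(y), collapse = "x"),
         " does not match network output ", paste(dim(out), collapse = "x"),
         call. = FALSE)
  }
  n <- ncol(out)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  # dLoss/d(output) for Loss = (1/N) sum (y - yhat)^2, N = number of samples
  delta <- (2 / n) * (out - y) * .act_deriv(cache$z[[n_layers]],
                                            model$activations[n_layers])
  for (l in rev(seq_len(n_layers))) {
    dW[[l]] <- delta %*% t(cache$a[[l]])
    db[[l]] <- rowSums(delta)
    if (l > 1L) {
      delta <- (t(model$weights[[l]]) %*% delta) *
        .act_deriv(cache$z[[l - 1L]], model$activations[l - 1L])
    }
  }
  list(dW = dW, db = db)
}

#' One gradient-descent step
#'
#' `W^l <- W^l - eta * dLoss/dW^l` (and likewise biases); nothing else is
#' mutated.
#'
#' @param model An `mlp_model`.
#' @param grads Gradients from [backward_mlp()].
#' @param eta Learning rate (> 0, or 0 for a null step).
#' @return The updated `mlp_model`.
#' @export
gd_step <- function(model, grads, eta) {
  stopifnot(inherits(model, "mlp_model"))
  for (l in seq_along(model$weights)) {
    if (!all(is.finite(grads$dW[[l]])) || !all(is.finite(grads$db[[l]]))) {
      stop("non-finite gradient at layer ", l,
           "; training diverged (try a smaller learning rate)", call. = FALSE)
    }
    model$weights[[l]] <- model$weights[[l]] - eta * grads$dW[[l]]
    model$biases[[l]] <- model$biases[[l]] - eta * grads$db[[l]]
  }
  model
}

#' Training configuration
#'
#' @param eta Learning rate of the weight-update rule (default 0.01).
#' @param max_epochs Maximum number of full-batch epochs (default 10000).
#' @param patience Early-stopping patience: stop after this many epochs
#'   without a validation-MSE improvement (default 1000). Full-batch descent
#'   at a small learning rate crosses long interim plateaus of the validation
#'   curve; a short patience halts on such a plateau while the network is
#'   still underfit, so the default is deliberately generous. Ignored when no
#'   validation set is supplied.
#' @return A `training_config` list.
#' @export
training_config <- function(eta = 0.01, max_epochs = 10000, patience = 1000) {
  if (eta < 0) stop("eta must be >= 0", call. = FALSE)
  if (max_epochs < 0) stop("max_epochs must be >= 0", call. = FALSE)
  structure(list(eta = eta, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "training_config")
}

.fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

.standardize <- function(x, std) {
  t((t(x) - std$center) / std$scale)
}

#' Train an MLP by full-batch gradient descent
#'
#' Features are z-scored with statistics fitted on the training set only
#' (raw feature scales differ by orders of magnitude and tansig saturates
#' without it); the statistics are stored inside the returned model. Targets
#' are the literal encodings 1 (healthy) and 2 (unhealthy) under squared
#' error. When a validation set is given, training stops early once
#' validation MSE has not improved for `patience` epochs and the
#' best-validation snapshot is returned.
#'
#' @param model An `mlp_model` (typically fresh from [init_mlp()]).
#' @param x_train Numeric matrix, one row per sample, columns = features.
#' @param y_train Numeric targets (1/2) or label strings.
#' @param x_val,y_val Optional validation set in the same layout.
#' @param config A [training_config()].
#' @return List with `model` (trained, standardizer attached) and `history`
#'   (data.frame: epoch, train_mse, val_mse).
#' @export
train_mlp <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      config = training_config()) {
  stopifnot(inherits(model, "mlp_model"), inherits(config, "training_config"))
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 1L) stop("empty training set", call. = FALSE)
  if (is.character(y_train)) y_train <- encode_labels(y_train)
  if (!is.null(y_val) && is.character(y_val)) y_val <- encode_labels(y_val)
  if (config$max_epochs == 0L) {
    return(list(model = model,
                history = data.frame(epoch = integer(0),
                                     train_mse = numeric(0),
                                     val_mse = numeric(0))))
  }

  std <- .fit_standardizer(x_train)
  model$standardizer <- std
  xt <- t(.standardize(x_train, std))          # features x n
  yt <- matrix(y_train, nrow = 1)
  has_val <- !is.null(x_val) && nrow(as.matrix(x_val)) > 0
  if (has_val) {
    xv <- t(.standardize(as.matrix(x_val), std))
    yv <- matrix(y_val, nrow = 1)
  }

  history <- data.frame(epoch = seq_len(config$max_epochs),
                        train_mse = NA_real_, val_mse = NA_real_)
  best_model <- model
  best_val <- Inf
  stale <- 0L
  n_done <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    cache <- forward_mlp(model, xt)
    train_mse <- mse_loss(yt, cache$a[[length(cache$a)]])
    if (!is.finite(train_mse)) {
      stop("training diverged (non-finite loss at epoch ", epoch,
           "); try a smaller learning rate", call. = FALSE)
    }
    grads <- backward_mlp(model, cache, yt)
    model <- gd_step(model, grads, config$eta)
    history$train_mse[epoch] <- train_mse
    n_done <- epoch
    if (has_val) {
      val_out <- forward_mlp(model, xv)$a
      val_mse <- mse_loss(yv, val_out[[length(val_out)]])
      history$val_mse[epoch] <- val_mse
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse
        best_model <- model
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    } else {
      best_model <- model
    }
  }
  list(model = best_model, history = history[seq_len(n_done), ])
}

#' Predict labels for new samples
#'
#' Standardizes inputs with the model's stored training statistics, runs the
#' forward pass, and thresholds the raw score at the model's threshold
#' (default 1.5): scores of at least the threshold are `"unhealthy"`. Inputs
#' far outside the training distribution (|z| > 10 after standardization)
#' trigger a warning, not an error.
#'
#' @param model A trained `mlp_model` (standardizer fitted).
#' @param x Numeric matrix, one row per sample, or a single-sample vector.
#' @return Data.frame with columns `score` and `label`.
#' @export
predict_mlp <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (!is.null(model$standardizer)) {
    x <- .standardize(x, model$standardizer)
    if (any(abs(x) > 10)) {
      warning("input lies far outside the training feature range ",
              "(|z| > 10 after standardization)", call. = FALSE)
    }
  }
  out <- forward_mlp(model, t(x))$a
  score <- as.numeric(out[[length(out)]])
  data.frame(score = score, label = decode_scores(score, model$threshold),
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint stores layer sizes, row-major weight arrays, biases,
#' activation tags, the feature-standardization statistics and the decision
#' threshold.
#'
#' @param model An `mlp_model`.
#' @param path JSON path.
#' @return `load_model` returns the `mlp_model`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    layer_sizes = model$layer_sizes,
    weights = lapply(model$weights, function(w) {
      list(nrow = nrow(w), ncol = ncol(w), data = as.numeric(t(w)))
    }),
    biases = model$biases,
    activations = model$activations,
    standardizer = model$standardizer,
    threshold = model$threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(nrow(obj$weights)), function(i) {
    matrix(obj$weights$data[[i]], nrow = obj$weights$nrow[i], byrow = TRUE)
  })
  std <- obj$standardizer
  if (!is.null(std)) std <- list(center = std$center, scale = std$scale)
  structure(
    list(layer_sizes = as.integer(obj$layer_sizes), weights = weights,
         biases = lapply(obj$biases, as.numeric),
         activations = as.character(obj$activations),
         standardizer = std, threshold = obj$threshold),
    class = "mlp_model"
  )
}
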