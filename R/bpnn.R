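#' BPNN training configuration
#'
#' The network and optimizer settings of the backpropagation regressor:
#' sigmoid hidden layers, an identity output unit, and per-sample
#' (incremental) gradient descent on the squared error with a fixed learning
#' rate. One "iteration" is one epoch: a full presentation of the training
#' set in row order.
#'
#' The default topology is a single hidden layer of 5 nodes (a three-layer
#' network counting input and output layers), which trains reliably within
#' the 100-epoch budget; a deeper stack is available as
#' `hidden_layers = c(5, 5, 5)`.
#'
#' @param hidden_layers integer vector of hidden-layer node counts.
#' @param learning_rate gradient-descent step size (> 0; default 0.1).
#' @param max_iterations training epochs (default 100); 0 leaves the network
#'   at its random initialization.
#' @param target_rmse early-stop threshold on the training RMSE in scaled
#'   (0--1) target units (default 0.00004); a non-finite value (e.g. `Inf`)
#'   disables early stopping, so training runs exactly `max_iterations`
#'   epochs.
#' @param seed default seed for weight initialization.
#' @return list of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden_layers = 5L, learning_rate = 0.1,
                        max_iterations = 100L, target_rmse = 0.00004,
                        seed = 1L) {
  hidden_layers <- as.integer(hidden_layers)
  if (length(hidden_layers) < 1L || any(hidden_layers < 1L))
    stop("hidden_layers must be positive counts", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (max_iterations < 0L) stop("max_iterations must be >= 0", call. = FALSE)
  structure(list(hidden_layers = hidden_layers, learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 target_rmse = target_rmse, seed = as.integer(seed)),
            class = "bpnn_config")
}

# min-max scaler: degenerate (constant) columns map to 0.5
minmax_fit <- function(X) {
  X <- as.matrix(X)
  list(lo = apply(X, 2, min), hi = apply(X, 2, max))
}

minmax_apply <- function(scaler, X) {
  X <- as.matrix(X)
  span <- scaler$hi - scaler$lo
  out <- sweep(sweep(X, 2, scaler$lo), 2, ifelse(span > 0, span, 1), "/")
  out[, span <= 0] <- 0.5
  out
}

# initial weights/biases ~ uniform(-0.5, 0.5), layer by layer, from seed
bpnn_init <- function(sizes, seed) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -0.5, 0.5),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- runif(sizes[l + 1L], -0.5, 0.5)
    }
    list(W = W, b = b)
  })
}

#' Train a backpropagation neural-network regressor
#'
#' Inputs and targets are min--max scaled to `[0, 1]` using the training
#' data; weights and biases start at uniform(-0.5, 0.5) draws from `seed`;
#' training presents samples one at a time in row order and applies the
#' delta-rule update after each, for up to `max_iterations` epochs or until
#' the training RMSE (scaled units) reaches `target_rmse`. Deterministic for
#' a fixed seed.
#'
#' @param X numeric matrix of predictors (e.g. PC scores), samples x features.
#' @param y numeric response vector (mg/100 g); must have positive range.
#' @param config a [bpnn_config()].
#' @param seed weight-initialization seed (default `config$seed`).
#' @return list of class `bpnn_model`: weights `W`, biases `b`, the input and
#'   target scalers, `config`, `seed`, epochs run and the per-epoch training
#'   RMSE trace (scaled units).
#' @export
bpnn_train <- function(X, y, config = bpnn_config(), seed = config$seed) {
  stopifnot(inherits(config, "bpnn_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (max(y) - min(y) <= 0)
    stop("degenerate response: y has zero range", call. = FALSE)
  in_scaler <- minmax_fit(X)
  t_scaler <- list(lo = min(y), hi = max(y))
  Xs <- minmax_apply(in_scaler, X)
  ys <- (y - t_scaler$lo) / (t_scaler$hi - t_scaler$lo)
  sizes <- c(ncol(X), config$hidden_layers, 1L)
  net <- bpnn_init(sizes, seed)
  if (config$max_iterations > 0L) {
    fit <- cpp_bpnn_train(Xs, ys, net$W, net$b, config$learning_rate,
                          config$max_iterations, config$target_rmse)
    net <- list(W = fit$W, b = fit$b)
    epochs <- fit$epochs
    trace <- fit$rmse_trace
  } else {
    epochs <- 0L
    trace <- numeric(0)
  }
  structure(list(W = net$W, b = net$b, input_scaler = in_scaler,
                 target_scaler = t_scaler, config = config,
                 seed = as.integer(seed), epochs = epochs,
                 rmse_trace = trace),
            class = "bpnn_model")
}

#' Predict from a trained BPNN
#'
#' Applies the training input scaler, runs the forward pass, and maps the
#' scaled output back to mg/100 g with the training target scaler.
#'
#' @param model a [bpnn_train()] result.
#' @param X matrix with the training feature dimension.
#' @return numeric vector of predictions, mg/100 g.
#' @export
bpnn_predict <- function(model, X) {
  stopifnot(inherits(model, "bpnn_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$input_scaler$lo))
    stop("feature dimension (", ncol(X), ") does not match the model (",
         length(model$input_scaler$lo), ")", call. = FALSE)
  Xs <- minmax_apply(model$input_scaler, X)
  out <- as.numeric(cpp_bpnn_forward(Xs, model$W, model$b))
  model$target_scaler$lo +
    out * (model$target_scaler$hi - model$target_scaler$lo)
}

#' Training loss and analytic gradient (scaled units)
#'
#' The loss is the mean over samples of half the squared error on the scaled
#' target; `bpnn_gradient()` returns its exact analytic gradient with respect
#' to every weight matrix and bias vector, computed by backpropagation. These
#' operate on already-scaled data and are exposed mainly so the gradient can
#' be verified against finite differences.
#'
#' @param Xs scaled input matrix; `ys` scaled target vector.
#' @param W,b lists of weight matrices and bias vectors.
#' @return `bpnn_loss()`: a scalar; `bpnn_gradient()`: list with `gW`, `gb`.
#' @export
bpnn_loss <- function(Xs, ys, W, b) {
  cpp_bpnn_loss(as.matrix(Xs), as.numeric(ys), W, b)
}

#' @rdname bpnn_loss
#' @export
bpnn_gradient <- function(Xs, ys, W, b) {
  cpp_bpnn_grad(as.matrix(Xs), as.numeric(ys), W, b)
}
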