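#' Configuration for the backpropagation network
#'
#' A single-hidden-layer perceptron with logistic-sigmoid activations
#' throughout and one output unit read as P(diabetic | x). Training is
#' classic per-sample (stochastic) backpropagation: weights are initialized
#' uniformly in (-init_range, +init_range) from `seed`, samples are visited
#' in a freshly shuffled order each epoch, and training stops after `epochs`
#' epochs or once the epoch sum-of-squares error improves by less than
#' `tolerance`.
#'
#' @param n_hidden hidden units (default 8).
#' @param learning_rate step size applied to the raw weight increments.
#' @param epochs maximum training epochs.
#' @param init_range half-width of the uniform weight initialization.
#' @param seed integer RNG seed controlling initialization and shuffling.
#' @param tolerance early-stop threshold on the epoch SSE change.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(n_hidden = 8L, learning_rate = 0.5, epochs = 100L,
                       init_range = 0.5, seed = 1L, tolerance = 1e-6) {
  stopifnot(n_hidden >= 1, learning_rate > 0, epochs >= 1,
            init_range > 0, tolerance >= 0)
  structure(list(n_hidden = as.integer(n_hidden), learning_rate = learning_rate,
                 epochs = as.integer(epochs), init_range = init_range,
                 seed = as.integer(seed), tolerance = tolerance),
            class = "ann_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Construct an ANN model from explicit weights
#'
#' Mostly useful for tests and hand-built examples; [train_ann()] builds
#' models from data.
#'
#' @param W d x h input-to-hidden weight matrix.
#' @param b1 length-h hidden bias vector.
#' @param V h x 1 hidden-to-output weight matrix.
#' @param b2 output bias (length 1).
#' @return An object of class `ann_model`.
#' @export
ann_model <- function(W, b1, V, b2) {
  W <- as.matrix(W); V <- as.matrix(V)
  dimnames(W) <- NULL; dimnames(V) <- NULL
  b1 <- unname(b1); b2 <- unname(b2)
  stopifnot(length(b1) == ncol(W), nrow(V) == ncol(W), ncol(V) == 1L,
            length(b2) == 1L, all(is.finite(W)), all(is.finite(V)),
            all(is.finite(b1)), is.finite(b2))
  structure(list(W = W, b1 = as.numeric(b1), V = V, b2 = as.numeric(b2)),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat("ANN model:", nrow(x$W), "inputs ->", ncol(x$W), "hidden -> 1 output (sigmoid)\n")
  invisible(x)
}

#' Forward pass through the network
#'
#' Hidden pre-activations \eqn{f_j = b_{1j} + \sum_i w_{ij} r_i}, hidden
#' activations \eqn{\phi_j = \sigma(f_j)}, and likewise for the output unit.
#'
#' @param model an [ann_model()].
#' @param r input feature vector of length d.
#' @return list with `hidden` (length h) and `output` (scalar in (0,1)).
#' @export
forward <- function(model, r) {
  if (length(r) != nrow(model$W)) stop("input has wrong dimension")
  hidden <- sigmoid(drop(r %*% model$W) + model$b1)
  output <- sigmoid(sum(hidden * model$V[, 1]) + model$b2)
  list(hidden = hidden, output = output)
}

#' Sum-of-squares training error
#'
#' \eqn{E = \tfrac12 \sum_k (\tau_k - \phi_k)^2} between desired and computed
#' outputs.
#'
#' @param outputs computed outputs.
#' @param targets desired outputs.
#' @return non-negative scalar.
#' @export
sse_error <- function(outputs, targets) {
  if (length(outputs) != length(targets)) stop("length mismatch")
  0.5 * sum((targets - outputs)^2)
}

#' Raw backpropagation increments for one sample
#'
#' Output delta \eqn{\xi_k = (\tau_k - \phi_k)\phi_k(1-\phi_k)}, hidden delta
#' \eqn{\xi_j = (\sum_k \xi_k \nu_{jk})\phi_j(1-\phi_j)}, and raw increments
#' \eqn{\Delta\nu_{jk} = \xi_k \phi_j}, \eqn{\Delta w_{ij} = \xi_j r_i}
#' (unit step; the learning rate is applied by [update_weights()]). Adding
#' these increments moves the weights down the gradient of the sum-of-squares
#' error, i.e. \eqn{\Delta = -\partial E/\partial w}.
#'
#' @param model an [ann_model()].
#' @param r input feature vector.
#' @param target desired output (0 or 1).
#' @return list of increments `dW`, `db1`, `dV`, `db2` plus the forward pass.
#' @export
backprop_deltas <- function(model, r, target) {
  fw <- forward(model, r)
  o <- fw$output; h <- fw$hidden
  xi_k <- (target - o) * o * (1 - o)
  xi_j <- (model$V[, 1] * xi_k) * h * (1 - h)
  list(dW = outer(as.numeric(r), xi_j), db1 = xi_j,
       dV = matrix(xi_k * h, ncol = 1), db2 = xi_k, forward = fw)
}

#' Apply weight increments scaled by the learning rate
#'
#' \eqn{w^+ = w + \lambda_F \Delta w} and \eqn{\nu^+ = \nu + \lambda_F
#' \Delta\nu}, biases likewise.
#'
#' @param model an [ann_model()].
#' @param grads increments from [backprop_deltas()].
#' @param rate learning rate \eqn{\lambda_F}.
#' @return updated [ann_model()].
#' @export
update_weights <- function(model, grads, rate) {
  ann_model(model$W + rate * grads$dW, model$b1 + rate * grads$db1,
            model$V + rate * grads$dV, model$b2 + rate * grads$db2)
}

#' Train the network by stochastic backpropagation
#'
#' @param train a standardized, complete [labeled_dataset()]; targets are the
#'   {0,1} labels.
#' @param config an [ann_config()].
#' @return A trained [ann_model()] with attributes `sse_log` (per-epoch SSE)
#'   and `epochs_run`. Identical data + config yield bit-identical models.
#' @export
train_ann <- function(train, config = ann_config()) {
  X <- train$values
  if (anyNA(X)) stop("training data must be complete (imputed)")
  y <- as.numeric(train$labels)
  if (length(unique(y)) < 2L)
    warning("training data contains a single class; proceeding anyway")
  n <- nrow(X); d <- ncol(X); h <- config$n_hidden
  rng <- config$init_range
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  W <- matrix(stats::runif(d * h, -rng, rng), d, h)
  b1 <- stats::runif(h, -rng, rng)
  V <- matrix(stats::runif(h, -rng, rng), h, 1)
  b2 <- stats::runif(1, -rng, rng)
  lr <- config$learning_rate
  Vv <- V[, 1]

  sse_log <- numeric(config$epochs)
  prev_sse <- Inf
  epochs_run <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    sse <- 0
    for (i in ord) {
      r <- X[i, ]
      hid <- 1 / (1 + exp(-(drop(r %*% W) + b1)))
      o <- 1 / (1 + exp(-(sum(hid * Vv) + b2)))
      err <- y[i] - o
      sse <- sse + 0.5 * err * err
      xi_k <- err * o * (1 - o)
      xi_j <- (Vv * xi_k) * hid * (1 - hid)
      Vv <- Vv + lr * xi_k * hid
      b2 <- b2 + lr * xi_k
      W <- W + lr * outer(r, xi_j)
      b1 <- b1 + lr * xi_j
    }
    epochs_run <- ep
    sse_log[ep] <- sse
    if (abs(prev_sse - sse) < config$tolerance) break
    prev_sse <- sse
  }
  model <- ann_model(W, b1, matrix(Vv, ncol = 1), b2)
  attr(model, "sse_log") <- sse_log[seq_len(epochs_run)]
  attr(model, "epochs_run") <- epochs_run
  attr(model, "config") <- config
  model
}

#' Network posterior for the target (diabetic) class
#' @param model a trained [ann_model()].
#' @param x feature vector or matrix of row vectors.
#' @return posterior probabilities in (0, 1).
#' @export
ann_posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$W)) stop("query has wrong dimension")
  H <- sigmoid(sweep(x %*% model$W, 2, model$b1, "+"))
  drop(sigmoid(H %*% model$V + model$b2))
}

#' Predict hard labels with the network
#' @param model a trained [ann_model()].
#' @param x feature vector or matrix.
#' @return integer labels in {0, 1} (posterior >= 0.5 goes to diabetic).
#' @export
ann_predict <- function(model, x) as.integer(ann_posterior(model, x) >= 0.5)

#' Serialize an ANN model to JSON
#' @param model an [ann_model()].
#' @return JSON string with shapes and weight arrays.
#' @export
ann_to_json <- function(model) {
  jsonlite::toJSON(list(d = nrow(model$W), h = ncol(model$W),
                        W = unname(model$W), b1 = model$b1,
                        V = unname(model$V), b2 = model$b2),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize an ANN model from JSON
#' @param txt JSON string or path from [ann_to_json()].
#' @return An [ann_model()].
#' @export
ann_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  ann_model(matrix(o$W, o$d, o$h), o$b1, matrix(o$V, o$h, 1), o$b2)
}
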