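#' Kernel specification
#'
#' The four kernels used by the support-vector classifier:
#' linear \eqn{x^T z}, radial basis \eqn{\exp(-\gamma\|x-z\|^2)},
#' polynomial \eqn{(\gamma x^T z + r)^d}, and sigmoid
#' \eqn{\tanh(\gamma x^T z + r)}.
#'
#' @param kind one of `"linear"`, `"rbf"`, `"polynomial"`, `"sigmoid"`.
#' @param gamma positive scale (ignored by the linear kernel).
#' @param r additive constant for polynomial/sigmoid kernels.
#' @param d polynomial degree (integer >= 1).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = 1, r = 0, d = 3L) {
  kind <- match.arg(kind)
  if (kind != "linear" && gamma <= 0) stop("gamma must be positive")
  d <- as.integer(d)
  if (d < 1L) stop("degree must be >= 1")
  structure(list(kind = kind, gamma = gamma, r = r, d = d), class = "kernel_spec")
}

#' Evaluate a kernel on a pair of vectors
#' @param spec a [kernel_spec()].
#' @param x,z numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, z) {
  if (length(x) != length(z)) stop("kernel arguments have different dimensions")
  switch(spec$kind,
         linear = sum(x * z),
         rbf = exp(-spec$gamma * sum((x - z)^2)),
         polynomial = (spec$gamma * sum(x * z) + spec$r)^spec$d,
         sigmoid = tanh(spec$gamma * sum(x * z) + spec$r))
}

#' Kernel matrix between two sets of row vectors
#' @param spec a [kernel_spec()].
#' @param A,B numeric matrices with equal column counts.
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
kernel_matrix <- function(spec, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("kernel arguments have different dimensions")
  G <- A %*% t(B)
  switch(spec$kind,
         linear = G,
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
           exp(-spec$gamma * pmax(d2, 0))
         },
         polynomial = (spec$gamma * G + spec$r)^spec$d,
         sigmoid = tanh(spec$gamma * G + spec$r))
}

#' Train a soft-margin support vector machine
#'
#' Solves the dual problem
#' \deqn{\max_a \sum_i a_i - \tfrac12 \sum_{ij} a_i a_j y_i y_j K(x_i, x_j)}
#' subject to \eqn{0 \le a_i \le C} and \eqn{\sum_i a_i y_i = 0}, with dataset
#' label 1 (diabetic, the target class) mapped to \eqn{y = +1} and label 0 to
#' \eqn{y = -1}. The quadratic program is delegated to the libsvm solver
#' (via \pkg{e1071}); the returned model carries the support vectors, the
#' signed multipliers \eqn{a_i y_i} and the bias, oriented so that a positive
#' decision value votes for the diabetic class, and is checked against the
#' dual feasibility conditions on return.
#'
#' @param train a standardized, complete [labeled_dataset()] containing both
#'   classes.
#' @param C positive misclassification penalty.
#' @param kernel a [kernel_spec()]; `gamma = NULL` in [default_kernel()] picks
#'   1/d features.
#' @return An object of class `svm_model` with fields `support_vectors`,
#'   `dual_coefs` (\eqn{a_i y_i}), `b`, `kernel`, `C`.
#' @export
train_svm <- function(train, C = 1, kernel = default_kernel(train)) {
  if (C <= 0) stop("C must be positive")
  if (anyNA(train$values)) stop("training data must be complete (imputed)")
  y <- ifelse(train$labels == 1L, 1, -1)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  X <- train$values
  ek <- switch(kernel$kind, linear = "linear", rbf = "radial",
               polynomial = "polynomial", sigmoid = "sigmoid")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = ek,
                    cost = C, gamma = kernel$gamma, coef0 = kernel$r,
                    degree = kernel$d, scale = FALSE, tolerance = 1e-4,
                    fitted = FALSE)
  coefs <- as.numeric(fit$coefs)
  b <- -fit$rho
  # libsvm orients decision values toward its internal first class; flip so
  # that positive values always vote for y = +1 (diabetic)
  if (fit$levels[fit$labels[1]] == "-1") {
    coefs <- -coefs
    b <- -b
  }
  model <- structure(
    list(support_vectors = as.matrix(fit$SV), dual_coefs = coefs, b = b,
         kernel = kernel, C = C, n_features = ncol(X)),
    class = "svm_model"
  )
  stopifnot(all(abs(model$dual_coefs) <= C + 1e-6),
            abs(sum(model$dual_coefs)) < 1e-6)
  model
}

#' Default kernel for a dataset
#'
#' Radial basis function kernel with `gamma = 1/d` where d is the number of
#' features — the standard choice for this architecture.
#'
#' @param train a [labeled_dataset()] or feature count.
#' @return A [kernel_spec()].
#' @export
default_kernel <- function(train) {
  d <- if (inherits(train, "labeled_dataset")) ncol(train$values) else as.integer(train)
  kernel_spec("rbf", gamma = 1 / d)
}

#' @export
print.svm_model <- function(x, ...) {
  cat("SVM model:", nrow(x$support_vectors), "support vectors,",
      x$kernel$kind, "kernel, C =", x$C, "\n")
  invisible(x)
}

#' SVM decision values
#'
#' \eqn{f(x) = \sum_i a_i y_i K(x_i, x) + b} over the support vectors.
#' Positive values vote for the diabetic class (label 1).
#'
#' @param model an [svm_model][train_svm()].
#' @param x a feature vector or a matrix of row vectors.
#' @return numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features) stop("query has wrong dimension")
  if (nrow(model$support_vectors) == 0L) return(rep(model$b, nrow(x)))
  K <- kernel_matrix(model$kernel, x, model$support_vectors)
  unname(drop(K %*% model$dual_coefs)) + model$b
}

#' Predict hard labels with an SVM
#' @param model an [svm_model][train_svm()].
#' @param x feature vector or matrix.
#' @return integer labels in {0, 1}; the decision boundary f(x) = 0 goes to
#'   the diabetic class.
#' @export
svm_predict <- function(model, x) as.integer(decision_value(model, x) >= 0)

#' Dual objective value of a trained SVM
#'
#' \eqn{\sum_i a_i - \tfrac12 c^T K c} with \eqn{c_i = a_i y_i}, evaluated on
#' the support set (non-support points contribute nothing). Used to compare a
#' trained model against an independent solver.
#'
#' @param model an [svm_model][train_svm()].
#' @return scalar dual objective.
#' @export
dual_objective <- function(model) {
  cvec <- model$dual_coefs
  K <- kernel_matrix(model$kernel, model$support_vectors)
  sum(abs(cvec)) - 0.5 * drop(t(cvec) %*% K %*% cvec)
}

#' Fit a Platt-type sigmoid calibration
#'
#' Maps raw decision values f to posterior probabilities
#' \eqn{P(y=1\mid f) = 1/(1+\exp(Af+B))} by minimizing the cross-entropy
#' against the smoothed targets \eqn{t_+ = (N_+ + 1)/(N_+ + 2)} and
#' \eqn{t_- = 1/(N_- + 2)}. A damped Newton iteration from the fixed start
#' \eqn{A = 0, B = \log((N_-+1)/(N_+ +1))} makes the fit deterministic.
#'
#' @param decision_values numeric vector of finite decision values.
#' @param labels integer vector over {0, 1}, both classes present.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `platt_calibration` with fields `A`, `B`.
#' @export
fit_platt <- function(decision_values, labels, max_iter = 100L, tol = 1e-10) {
  f <- as.numeric(decision_values)
  if (any(!is.finite(f))) stop("decision values must be finite")
  y <- as.integer(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  t_hi <- (n_pos + 1) / (n_pos + 2)
  t_lo <- 1 / (n_neg + 2)
  t <- ifelse(y == 1L, t_hi, t_lo)

  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  nll <- function(A, B) {
    z <- A * f + B
    # -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z)), stable form
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  obj <- nll(A, B)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                 # dNLL/dz since p = sigma(-z)
    w <- p * (1 - p)
    gA <- sum(d1 * f); gB <- sum(d1)
    if (max(abs(gA), abs(gB)) < 1e-8) break
    hAA <- sum(w * f * f) + sigma
    hBB <- sum(w) + sigma
    hAB <- sum(w * f)
    det <- hAA * hBB - hAB^2
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(hAA * gB - hAB * gA) / det
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      new_obj <- nll(newA, newB)
      if (new_obj < obj + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (abs(new_obj - obj) < tol) { A <- newA; B <- newB; break }
    A <- newA; B <- newB; obj <- new_obj
  }
  structure(list(A = A, B = B), class = "platt_calibration")
}

#' Apply a Platt calibration to decision values
#' @param cal a [fit_platt()] calibration.
#' @param f numeric decision values.
#' @return posterior probabilities of the diabetic class in (0, 1).
#' @export
platt_posterior <- function(cal, f) {
  z <- cal$A * f + cal$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Calibrated SVM posterior for the target (diabetic) class
#' @param model an [svm_model][train_svm()].
#' @param cal a [fit_platt()] calibration.
#' @param x feature vector or matrix.
#' @return posterior probabilities in (0, 1).
#' @export
svm_posterior <- function(model, cal, x) platt_posterior(cal, decision_value(model, x))

#' Train an SVM with cross-validated Platt calibration
#'
#' Fits the SVM on all training rows, then fits the calibration sigmoid on
#' *out-of-fold* decision values from a small internal stratified
#' cross-validation. Calibrating on in-sample decision values would be
#' optimistic — a flexible kernel machine separates its own training data far
#' better than unseen data — and would distort the posterior scale the fusion
#' layer depends on.
#'
#' @param train a standardized, complete [labeled_dataset()].
#' @param C,kernel passed to [train_svm()].
#' @param cal_folds internal folds for calibration scores (default 3).
#' @param seed seed for the internal split.
#' @return list with `model` (the full-data [svm_model][train_svm()]) and
#'   `cal` (the [fit_platt()] calibration).
#' @export
calibrated_svm <- function(train, C = 1, kernel = default_kernel(train),
                           cal_folds = 3L, seed = 1L) {
  model <- train_svm(train, C = C, kernel = kernel)
  fa <- stratified_kfold(train$labels, K = cal_folds, seed = seed)
  f_oof <- rep(NA_real_, n_records(train))
  for (k in seq_len(cal_folds)) {
    hold <- fa$fold_index == k
    mk <- train_svm(subset_rows(train, !hold), C = C, kernel = kernel)
    f_oof[hold] <- decision_value(mk, train$values[hold, , drop = FALSE])
  }
  list(model = model, cal = fit_platt(f_oof, train$labels))
}

#' Serialize an SVM model (and optional calibration) to JSON
#' @param model an [svm_model][train_svm()].
#' @param cal optional [fit_platt()] calibration.
#' @return JSON string.
#' @export
svm_to_json <- function(model, cal = NULL) {
  obj <- list(kernel = unclass(model$kernel), C = model$C,
              support_vectors = unname(model$support_vectors),
              dual_coefs = model$dual_coefs, b = model$b,
              n_features = model$n_features)
  if (!is.null(cal)) obj$calibration <- list(A = cal$A, B = cal$B)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Deserialize an SVM model from JSON
#' @param txt JSON string or path from [svm_to_json()].
#' @return list with `model` and (possibly NULL) `cal`.
#' @export
svm_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  k <- obj$kernel
  model <- structure(
    list(support_vectors = matrix(obj$support_vectors, ncol = obj$n_features),
         dual_coefs = as.numeric(obj$dual_coefs), b = obj$b,
         kernel = kernel_spec(k$kind, k$gamma, k$r, k$d), C = obj$C,
         n_features = obj$n_features),
    class = "svm_model"
  )
  cal <- if (!is.null(obj$calibration))
    structure(list(A = obj$calibration$A, B = obj$calibration$B),
              class = "platt_calibration")
  list(model = model, cal = cal)
}
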