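# Independent oracles used by the unit and acceptance suites. These
# deliberately re-derive results through different code paths than the
# package implementation (naive nested loops, endpoint search, finite
# differences) so agreement is evidence, not tautology.

# --- Dempster combination by naive enumeration over focal pairs ------------

oracle_conflict <- function(m1, m2) {
  k <- 0
  for (i in seq_along(m1$focal))
    for (j in seq_along(m2$focal)) {
      common <- m1$focal[[i]][m1$focal[[i]] %in% m2$focal[[j]]]
      if (!length(common)) k <- k + m1$mass[i] * m2$mass[j]
    }
  k
}

oracle_combine <- function(m1, m2) {
  sets <- list()
  w <- numeric()
  k <- 0
  for (i in seq_along(m1$focal))
    for (j in seq_along(m2$focal)) {
      common <- sort(m1$focal[[i]][m1$focal[[i]] %in% m2$focal[[j]]])
      p <- m1$mass[i] * m2$mass[j]
      if (!length(common)) { k <- k + p; next }
      hit <- FALSE
      for (s in seq_along(sets))
        if (identical(sets[[s]], common)) { w[s] <- w[s] + p; hit <- TRUE; break }
      if (!hit) { sets[[length(sets) + 1L]] <- common; w <- c(w, p) }
    }
  list(sets = sets, mass = w / (1 - k), K = k)
}

# look up the implementation's mass for a given subset (0 if absent)
mass_of <- function(m, subset) {
  subset <- sort(subset)
  for (i in seq_along(m$focal))
    if (identical(m$focal[[i]], subset)) return(m$mass[i])
  0
}

random_mass <- function(frame, max_focal = 8L) {
  all_subsets <- unlist(lapply(seq_along(frame), function(k)
    combn(frame, k, simplify = FALSE)), recursive = FALSE)
  n_focal <- sample.int(min(max_focal, length(all_subsets)), 1)
  focal <- sample(all_subsets, n_focal)
  w <- stats::runif(n_focal)
  mass_function(frame, focal, w / sum(w))
}

# --- SVM dual by pairwise (SMO-style) coordinate ascent --------------------

oracle_dual_objective <- function(alpha, y, K) {
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(t(ay) %*% K %*% ay)
}

oracle_svm_dual <- function(X, y, C, kern, sweeps = 4000) {
  n <- length(y)
  K <- kernel_matrix(kern, X)
  alpha <- numeric(n)
  for (sweep in seq_len(sweeps)) {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      f <- drop(K %*% (alpha * y))
      Ei <- f[i] - y[i]; Ej <- f[j] - y[j]
      if (y[i] != y[j]) {
        L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
      } else {
        L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
      }
      if (H - L < 1e-14) next
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      aj_old <- alpha[j]; ai_old <- alpha[i]
      if (eta > 1e-12) {
        aj <- min(max(aj_old + y[j] * (Ei - Ej) / eta, L), H)
      } else {
        # flat direction: evaluate both endpoints
        best <- -Inf; aj <- aj_old
        for (cand in c(L, H)) {
          a2 <- alpha; a2[j] <- cand
          a2[i] <- ai_old + y[i] * y[j] * (aj_old - cand)
          val <- oracle_dual_objective(a2, y, K)
          if (val > best) { best <- val; aj <- cand }
        }
      }
      if (abs(aj - aj_old) > 1e-14) {
        alpha[j] <- aj
        alpha[i] <- ai_old + y[i] * y[j] * (aj_old - aj)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(alpha = alpha, objective = oracle_dual_objective(alpha, y, K))
}

# --- finite-difference gradient of the per-sample SSE ----------------------

ann_sample_error <- function(model, r, target) {
  sse_error(forward(model, r)$output, target)
}

fd_increments <- function(model, r, target, h = 1e-5) {
  # central finite differences of E; returned with a minus sign so they are
  # directly comparable to the raw backprop increments (Delta = -dE/dw)
  num <- function(get, set) {
    base <- get(model)
    out <- array(0, dim = if (is.null(dim(base))) length(base) else dim(base))
    for (idx in seq_along(base)) {
      up <- base; up[idx] <- up[idx] + h
      dn <- base; dn[idx] <- dn[idx] - h
      out[idx] <- -(ann_sample_error(set(model, up), r, target) -
                      ann_sample_error(set(model, dn), r, target)) / (2 * h)
    }
    out
  }
  list(
    dW = num(function(m) m$W, function(m, v) { m$W <- matrix(v, nrow(m$W)); m }),
    db1 = num(function(m) m$b1, function(m, v) { m$b1 <- as.numeric(v); m }),
    dV = num(function(m) m$V, function(m, v) { m$V <- matrix(v, ncol = 1); m }),
    db2 = num(function(m) m$b2, function(m, v) { m$b2 <- as.numeric(v); m })
  )
}

random_ann <- function(d, h, seed) {
  set.seed(seed)
  ann_model(matrix(rnorm(d * h), d, h), rnorm(h), matrix(rnorm(h), h, 1), rnorm(1))
}

# --- small synthetic fixtures ----------------------------------------------

# two-feature Gaussian blobs with a custom schema (for base-classifier tests)
make_blobs2 <- function(n, gap_sd = 4, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  x <- cbind(rnorm(n, y * gap_sd), rnorm(n, y * gap_sd))
  sc <- feature_schema(data.frame(name = c("X1", "X2"),
                                  kind = c("real", "real"),
                                  unit = c("", "")))
  labeled_dataset(scale(x), y, "blobs", sc)
}

# standardized eight-feature dataset from the synthetic generator
make_std_dataset <- function(n, separation = 1, seed = 1, prevalence = 0.335,
                             missing_rate = 0) {
  spec <- synthetic_spec(sources = c(src = as.integer(n)), prevalence = prevalence,
                         separation = separation, missing_rate = missing_rate,
                         seed = seed)
  ds <- mark_missing(generate_sources(spec)[[1]])
  fit_preprocessor(ds)$transform(ds)
}

# hand-built SVM model without going through training
hand_svm_model <- function(support_vectors, dual_coefs, b, kernel) {
  structure(list(support_vectors = as.matrix(support_vectors),
                 dual_coefs = dual_coefs, b = b, kernel = kernel,
                 C = Inf, n_features = ncol(as.matrix(support_vectors))),
            class = "svm_model")
}

# constant-posterior fusion member (for fusion-layer tests)
fixed_member <- function(p) {
  structure(list(p = p), class = c("fixed_member", "fusion_member"))
}
posterior_target.fixed_member <- function(member, x) {
  rep(member$p, if (is.null(dim(x))) 1 else nrow(x))
}
registerS3method("posterior_target", "fixed_member", posterior_target.fixed_member,
                 envir = asNamespace("diafusion"))
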