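#' Derive a stage-specific seed from a master seed
#'
#' Stable arithmetic hash mixing the master seed with a stage tag so that
#' every random stage of the pipeline is independently reproducible from one
#' integer. Result is always in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param tag character stage tag.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) %% 1e6 * 7919 + h * 104729 + 17) %% 2147483646 + 1)
}

#' Stratified K-fold assignment
#'
#' Each class is shuffled independently (from `seed`) and dealt round-robin
#' across the K folds, so every fold's class-1 share stays within 1/(fold
#' size) of the overall share.
#'
#' @param labels integer vector over {0, 1}.
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return An object of class `fold_assignment`: list with `fold_index`
#'   (length n, values 1..K), `K`, `seed`.
#' @export
stratified_kfold <- function(labels, K = 5L, seed = 1L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  labels <- as.integer(labels)
  n <- length(labels)
  cnt <- table(factor(labels, levels = c(0, 1)))
  if (any(cnt < K))
    stop("each class needs at least K members (class sizes ",
         paste(cnt, collapse = "/"), ", K = ", K, ")")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  structure(list(fold_index = fold, K = K, seed = seed), class = "fold_assignment")
}

#' Hyperparameter grid for the two base classifiers
#'
#' @param svm_C candidate penalty values.
#' @param svm_gamma candidate RBF widths (`NA` entries become 1/d at fit time).
#' @param ann_hidden candidate hidden-layer sizes.
#' @param ann_rate candidate learning rates.
#' @return An object of class `grid_spec` with data.frames `svm` and `ann`.
#' @export
grid_spec <- function(svm_C = c(0.1, 1, 10, 100),
                      svm_gamma = c(0.01, 0.1, NA, 1),
                      ann_hidden = c(4L, 8L, 16L),
                      ann_rate = c(0.1, 0.5)) {
  svm <- expand.grid(C = svm_C, gamma = svm_gamma, KEEP.OUT.ATTRS = FALSE)
  ann <- expand.grid(n_hidden = as.integer(ann_hidden), rate = ann_rate,
                     KEEP.OUT.ATTRS = FALSE)
  if (!nrow(svm) || !nrow(ann)) stop("grids must be non-empty")
  structure(list(svm = svm, ann = ann), class = "grid_spec")
}

.resolve_gamma <- function(gamma, d) if (is.na(gamma)) 1 / d else gamma

.fit_eval_svm <- function(tr, te, C, gamma) {
  kern <- kernel_spec("rbf", gamma = .resolve_gamma(gamma, ncol(tr$values)))
  m <- train_svm(tr, C = C, kernel = kern)
  mean(svm_predict(m, te$values) == te$labels)
}

.fit_eval_ann <- function(tr, te, n_hidden, rate, epochs, seed) {
  cfg <- ann_config(n_hidden = n_hidden, learning_rate = rate,
                    epochs = epochs, seed = seed)
  m <- train_ann(tr, cfg)
  mean(ann_predict(m, te$values) == te$labels)
}

#' Inner-loop grid search for SVM and ANN hyperparameters
#'
#' Evaluates each candidate by mean accuracy over an inner stratified K-fold
#' split of the training data, with imputation and standardization refit on
#' every inner training fold. Ties are broken by grid order (first wins), so
#' the choice is deterministic given the seed.
#'
#' @param train a [labeled_dataset()] (raw scale, missing cells allowed).
#' @param grid a [grid_spec()].
#' @param inner_k inner fold count (default 3).
#' @param seed integer seed for the inner folds.
#' @param ann_epochs training epochs used for ANN candidates.
#' @return list with `svm` (C, gamma), `ann` (n_hidden, rate) and the scored
#'   candidate tables.
#' @export
grid_search <- function(train, grid, inner_k = 3L, seed = 1L, ann_epochs = 40L) {
  stopifnot(inherits(grid, "grid_spec"))
  folds <- stratified_kfold(train$labels, K = inner_k, seed = derive_seed(seed, "inner"))
  splits <- lapply(seq_len(inner_k), function(k) {
    tr <- subset_rows(train, folds$fold_index != k)
    te <- subset_rows(train, folds$fold_index == k)
    prep <- fit_preprocessor(tr)
    list(tr = prep$transform(tr), te = prep$transform(te))
  })
  score <- function(fit_eval, cands, ...) {
    vapply(seq_len(nrow(cands)), function(i) {
      mean(vapply(splits, function(s)
        do.call(fit_eval, c(list(s$tr, s$te), as.list(cands[i, ]), list(...))), 0))
    }, 0)
  }
  svm_scores <- score(.fit_eval_svm, grid$svm)
  ann_scores <- score(.fit_eval_ann, grid$ann,
                      epochs = ann_epochs, seed = derive_seed(seed, "ann-inner"))
  svm_best <- which.max(svm_scores)   # which.max returns the first maximum
  ann_best <- which.max(ann_scores)
  list(svm = as.list(grid$svm[svm_best, ]),
       ann = as.list(grid$ann[ann_best, ]),
       svm_scores = cbind(grid$svm, accuracy = svm_scores),
       ann_scores = cbind(grid$ann, accuracy = ann_scores))
}

#' Mean and sample standard deviation over folds
#'
#' The final performance aggregate: arithmetic mean of the per-fold metric
#' plus/minus its sample standard deviation (K - 1 denominator).
#'
#' @param per_fold_values numeric vector of K >= 2 per-fold values.
#' @return list with `mean` and `sd`.
#' @export
cv_aggregate <- function(per_fold_values) {
  if (length(per_fold_values) < 2L) stop("need at least two folds to aggregate")
  list(mean = mean(per_fold_values), sd = stats::sd(per_fold_values))
}

#' Stratified nested cross-validation of the full architecture
#'
#' Outer loop: stratified K folds. Per outer fold the held-out test rows are
#' untouched while (i) [grid_search()] selects SVM and ANN hyperparameters on
#' the outer-training rows via an inner stratified split, (ii) imputation and
#' standardization are fit on the outer-training rows, (iii) the SVM (with
#' Platt calibration), the network, and the fusion layer (priors = training
#' class frequencies) are trained, and (iv) all three classifiers are scored
#' on the transformed test fold. Metrics are reported per fold, as
#' mean +/- sample SD over folds, and pooled over the concatenated fold
#' predictions.
#'
#' @param ds a [labeled_dataset()] (raw scale; run [mark_missing()] first if
#'   zeros encode missingness).
#' @param grid a [grid_spec()].
#' @param K outer folds (default 5).
#' @param inner_k inner folds for the grid search (default 3).
#' @param seed master seed.
#' @param ann_epochs epochs for the final per-fold ANN fits (inner-loop
#'   candidate fits use the same value).
#' @param rule,mode,theta_i fusion-layer settings (see [fusion_model()]).
#' @return An object of class `cv_report`: per-fold metrics data.frame,
#'   aggregates, pooled metrics, chosen hyperparameters, fold assignment,
#'   per-fold preprocessing statistics, and pooled predictions.
#' @export
nested_cv <- function(ds, grid = grid_spec(), K = 5L, inner_k = 3L, seed = 1L,
                      ann_epochs = 40L, rule = "mean", mode = "mean_posterior",
                      theta_i = 1) {
  folds <- stratified_kfold(ds$labels, K = K, seed = derive_seed(seed, "outer"))
  per_fold <- list()
  chosen <- list()
  prep_stats <- list()
  pooled <- data.frame()
  for (k in seq_len(K)) {
    tr_idx <- which(folds$fold_index != k)
    te_idx <- which(folds$fold_index == k)
    tr <- subset_rows(ds, tr_idx)
    te <- subset_rows(ds, te_idx)

    sel <- grid_search(tr, grid, inner_k = inner_k,
                       seed = derive_seed(seed, paste0("fold", k)),
                       ann_epochs = ann_epochs)
    prep <- fit_preprocessor(tr)
    tr_z <- prep$transform(tr)
    te_z <- prep$transform(te)

    kern <- kernel_spec("rbf", gamma = .resolve_gamma(sel$svm$gamma, ncol(tr_z$values)))
    svm_cal <- calibrated_svm(tr_z, C = sel$svm$C, kernel = kern,
                              seed = derive_seed(seed, paste0("platt", k)))
    svm_fit <- svm_cal$model
    cal <- svm_cal$cal
    ann_fit <- train_ann(tr_z, ann_config(n_hidden = sel$ann$n_hidden,
                                          learning_rate = sel$ann$rate,
                                          epochs = ann_epochs,
                                          seed = derive_seed(seed, paste0("ann-final", k))))
    fm <- fit_fusion(list(svm_member(svm_fit, cal), ann_member(ann_fit)),
                     tr_z$labels, theta_i = theta_i, rule = rule, mode = mode)

    preds <- list(svm = svm_predict(svm_fit, te_z$values),
                  ann = ann_predict(ann_fit, te_z$values),
                  fusion = fusion_classify(fm, te_z$values)$label)
    for (cls in names(preds)) {
      mr <- suppressWarnings(metrics(confusion(te_z$labels, preds[[cls]])))
      per_fold[[length(per_fold) + 1L]] <-
        cbind(data.frame(fold = k, classifier = cls), as.data.frame(mr[.metric_names]))
    }
    pooled <- rbind(pooled, data.frame(index = te_idx, fold = k, truth = te_z$labels,
                                       svm = preds$svm, ann = preds$ann,
                                       fusion = preds$fusion,
                                       mu_target = fusion_classify(fm, te_z$values)$mu_target))
    chosen[[k]] <- sel[c("svm", "ann")]
    prep_stats[[k]] <- list(train_index = tr_idx, test_index = te_idx,
                            impute_means = prep$imputer$means,
                            location = prep$standardizer$location,
                            scale = prep$standardizer$scale)
  }
  per_fold <- do.call(rbind, per_fold)
  aggregate <- lapply(split(per_fold, per_fold$classifier), function(df) {
    sapply(.metric_names, function(m) unlist(cv_aggregate(df[[m]])))
  })
  pooled_metrics <- lapply(c(svm = "svm", ann = "ann", fusion = "fusion"), function(cls)
    suppressWarnings(metrics(confusion(pooled$truth, pooled[[cls]]))))
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 pooled_metrics = pooled_metrics, chosen = chosen,
                 folds = folds, prep_stats = prep_stats,
                 predictions = pooled, K = K, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested cross-validation report (K =", x$K, ")\n")
  for (cls in names(x$aggregate)) {
    acc <- x$aggregate[[cls]][, "accuracy"]
    cat(sprintf("  %-7s accuracy %.2f%% +/- %.2f (pooled %.2f%%)\n", cls,
                acc[["mean"]], acc[["sd"]], x$pooled_metrics[[cls]]$accuracy))
  }
  invisible(x)
}

#' Serialize a CV report to JSON
#' @param report a [nested_cv()] report.
#' @return JSON string.
#' @export
cv_report_to_json <- function(report) {
  obj <- list(
    K = report$K, seed = report$seed,
    per_fold = report$per_fold,
    aggregate = lapply(report$aggregate, function(m) as.data.frame(t(m))),
    pooled = lapply(report$pooled_metrics, function(r) unclass(r)),
    chosen = report$chosen
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
}
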