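test_that("stratified folds preserve class proportions", {
  labels <- rep(c(0L, 1L), c(60, 40))
  fa <- stratified_kfold(labels, K = 5, seed = 3)
  for (k in 1:5) {
    idx <- which(fa$fold_index == k)
    expect_equal(length(idx), 20L)
    expect_equal(sum(labels[idx] == 1L), 8L)   # exact divisibility: 12 + 8
  }
  # union of folds is the full index set, folds disjoint
  expect_equal(sort(unlist(lapply(1:5, function(k) which(fa$fold_index == k)))),
               seq_along(labels))
  # K = 2 on (1,1,0,0): one of each class per fold
  fa2 <- stratified_kfold(c(1L, 1L, 0L, 0L), K = 2, seed = 1)
  for (k in 1:2)
    expect_equal(sort(c(1L, 1L, 0L, 0L)[fa2$fold_index == k]), c(0L, 1L))
  expect_error(stratified_kfold(rep(c(0L, 1L), c(50, 3)), K = 5), "at least K")
  # determinism
  expect_identical(stratified_kfold(labels, 5, seed = 9)$fold_index,
                   stratified_kfold(labels, 5, seed = 9)$fold_index)
})

test_that("stratification bound holds across many seeds", {
  set.seed(6)
  labels <- rbinom(173, 1, 0.34)
  p_all <- mean(labels)
  for (seed in 1:50) {
    fa <- stratified_kfold(labels, K = 5, seed = seed)
    for (k in 1:5) {
      idx <- which(fa$fold_index == k)
      expect_lte(abs(mean(labels[idx]) - p_all), 1 / length(idx) + 1e-12)
    }
  }
})

test_that("grid search picks the better candidate deterministically", {
  spec <- synthetic_spec(sources = c(s = 240L), separation = 2.5, seed = 19,
                         missing_rate = 0.05)
  tr <- mark_missing(generate_sources(spec)[[1]])
  # a reasonable SVM candidate versus one whose tiny C forces the majority vote
  grid <- grid_spec(svm_C = c(1e-6, 10), svm_gamma = NA,
                    ann_hidden = 4L, ann_rate = 0.5)
  sel <- grid_search(tr, grid, inner_k = 2, seed = 5, ann_epochs = 10L)
  expect_equal(sel$svm$C, 10)
  expect_gt(sel$svm_scores$accuracy[2], sel$svm_scores$accuracy[1])
  # single-candidate grids return that candidate
  solo <- grid_search(tr, grid_spec(svm_C = 1, svm_gamma = 0.1,
                                    ann_hidden = 4L, ann_rate = 0.5),
                      inner_k = 2, seed = 5, ann_epochs = 5L)
  expect_equal(solo$svm, list(C = 1, gamma = 0.1))
  expect_equal(solo$ann, list(n_hidden = 4L, rate = 0.5))
  # repeated run with the same seed makes the same choice
  sel2 <- grid_search(tr, grid, inner_k = 2, seed = 5, ann_epochs = 10L)
  expect_identical(sel[c("svm", "ann")], sel2[c("svm", "ann")])
  expect_error(grid_spec(svm_C = numeric(0)), "non-empty")
})

test_that("fold aggregation is the mean plus/minus the sample SD", {
  expect_equal(cv_aggregate(c(1, 1, 1)), list(mean = 1, sd = 0))
  agg <- cv_aggregate(c(0.8, 0.9, 1.0))
  expect_equal(agg$mean, 0.9)
  expect_equal(agg$sd, 0.1, tolerance = 1e-12)
  expect_equal(cv_aggregate(c(1.0, 0.8, 0.9)), agg)
  expect_error(cv_aggregate(0.9), "two folds")
})

test_that("nested CV evaluates three classifiers per fold without leakage", {
  spec <- synthetic_spec(sources = c(s = 300L), separation = 2, seed = 23,
                         missing_rate = 0.05)
  ds <- mark_missing(generate_sources(spec)[[1]])
  grid <- grid_spec(svm_C = 1, svm_gamma = NA, ann_hidden = 4L, ann_rate = 0.5)
  cv <- nested_cv(ds, grid, K = 5, inner_k = 2, seed = 7, ann_epochs = 15L)
  expect_equal(nrow(cv$per_fold), 15L)  # 5 folds x 3 classifiers
  expect_setequal(unique(cv$per_fold$classifier), c("svm", "ann", "fusion"))
  # aggregate mean equals the mean of the per-fold metric
  for (cls in c("svm", "ann", "fusion")) {
    acc <- cv$per_fold$accuracy[cv$per_fold$classifier == cls]
    expect_equal(unname(cv$aggregate[[cls]]["mean", "accuracy"]), mean(acc),
                 tolerance = 1e-12)
    expect_equal(unname(cv$aggregate[[cls]]["sd", "accuracy"]), sd(acc),
                 tolerance = 1e-12)
  }
  # every record is scored exactly once across the outer folds
  expect_equal(sort(cv$predictions$index), seq_len(n_records(ds)))
  # leakage guard: the stored preprocessing statistics are reproduced from
  # the training rows alone, and train/test indices never overlap
  for (k in 1:5) {
    ps <- cv$prep_stats[[k]]
    expect_length(intersect(ps$train_index, ps$test_index), 0)
    tr <- subset_rows(ds, ps$train_index)
    expect_equal(ps$impute_means, fit_imputer(tr)$means)
    std <- fit_standardizer(impute(fit_imputer(tr), tr))
    expect_equal(ps$location, std$location)
    expect_equal(ps$scale, std$scale)
  }
  # identical seed reproduces the full report
  cv2 <- nested_cv(ds, grid, K = 5, inner_k = 2, seed = 7, ann_epochs = 15L)
  expect_equal(cv$per_fold, cv2$per_fold)
  expect_identical(cv$chosen, cv2$chosen)
  # JSON serialization parses back
  js <- jsonlite::fromJSON(cv_report_to_json(cv))
  expect_equal(js$K, 5)
  expect_named(js$pooled, c("svm", "ann", "fusion"))
})
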