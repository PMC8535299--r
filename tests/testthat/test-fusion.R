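test_that("combining rules follow their definitions and ordering", {
  expect_equal(combine_rule(c(0.8, 0.6), "mean"), 0.7)
  expect_equal(combine_rule(c(0.5, 0.5), "mean"), 0.5)
  expect_equal(combine_rule(c(0.5, 0.5), "min"), 0.5)
  expect_equal(combine_rule(c(0.5, 0.5), "max"), 0.5)
  expect_equal(combine_rule(c(0.5, 0.5), "product"), 0.25)
  # single member: every rule is the identity
  for (r in c("mean", "min", "max", "product"))
    expect_equal(combine_rule(0.37, r), 0.37)
  expect_error(combine_rule(numeric(0)), "empty")
  # product <= min <= mean <= max on random probability vectors
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(2:5, 1))
    expect_lte(combine_rule(p, "product"), combine_rule(p, "min") + 1e-12)
    expect_lte(combine_rule(p, "min"), combine_rule(p, "mean") + 1e-12)
    expect_lte(combine_rule(p, "mean"), combine_rule(p, "max") + 1e-12)
    # mean rule equals a naive elementwise average
    expect_equal(combine_rule(p, "mean"), sum(p) / length(p), tolerance = 1e-12)
  }
})

test_that("the outlier threshold is the prior odds times the mean density level", {
  expect_equal(fusion_threshold(class_priors(0.5), c(1, 1)), 1)
  expect_equal(fusion_threshold(class_priors(0.5), c(2, 4)), 3)
  # study prevalence: P(outlier)/P(target) = 0.665/0.335
  th <- fusion_threshold(class_priors(0.335), c(1, 1))
  expect_equal(th, 0.665 / 0.335, tolerance = 1e-12)
  expect_equal(round(th, 3), 1.985)
  expect_error(fusion_threshold(class_priors(0.335), c(1, -1)), "positive")
  expect_error(class_priors(0), "inside")
  expect_error(class_priors(0.4, 0.7), "sum to 1")
})

test_that("fusion decisions compare posteriors with ties to the target class", {
  fm <- function(p1, p2, ...) fusion_model(list(fixed_member(p1), fixed_member(p2)),
                                           class_priors(0.5), ...)
  x <- matrix(0, 1, 8)
  d <- fusion_classify(fm(0.9, 0.8), x)
  expect_equal(d$label, 1L)
  expect_equal(d$mu_target, 0.85)
  expect_equal(d$mu_outlier, 0.15)
  expect_equal(fusion_classify(fm(0.2, 0.3), x)$label, 0L)
  # equality goes to the target class (the outlier criterion is strict)
  expect_equal(fusion_classify(fm(0.5, 0.5), x)$label, 1L)
  # member posteriors are delegated in member order and clipped
  mp <- member_posteriors(fm(0.9, 0.2), x)
  expect_equal(drop(mp), c(0.9, 0.2))
  mp2 <- member_posteriors(fm(1, 0), x)
  expect_true(all(mp2 > 0 & mp2 < 1))
  # mu_target + mu_outlier = 1 under the mean rule
  set.seed(4)
  for (i in 1:20) {
    d <- fusion_classify(fm(runif(1), runif(1)), x)
    expect_equal(d$mu_target + d$mu_outlier, 1, tolerance = 1e-9)
  }
})

test_that("the density proxy is the mean posterior over the target prior", {
  fm <- fusion_model(list(fixed_member(0.5), fixed_member(0.5)), class_priors(0.5))
  expect_equal(average_density(fm, matrix(0, 1, 8)), 1)
  fm1 <- fusion_model(list(fixed_member(0.3)), class_priors(0.4))
  expect_equal(average_density(fm1, matrix(0, 1, 8)), 0.3 / 0.4)
  # monotone in the mean posterior across real members
  ds <- make_std_dataset(150, seed = 41)
  svm_fit <- train_svm(ds, C = 1)
  cal <- fit_platt(decision_value(svm_fit, ds$values), ds$labels)
  ann_fit <- train_ann(ds, ann_config(epochs = 20L, seed = 2))
  fmr <- fit_fusion(list(svm_member(svm_fit, cal), ann_member(ann_fit)), ds$labels)
  mp <- rowMeans(member_posteriors(fmr, ds$values))
  ord <- order(mp)
  expect_true(all(diff(average_density(fmr, ds$values)[ord]) >= -1e-12))
})

test_that("density-threshold mode matches the threshold criterion and sweeps monotonically", {
  ds <- make_std_dataset(300, seed = 43)
  svm_fit <- train_svm(ds, C = 1)
  cal <- fit_platt(decision_value(svm_fit, ds$values), ds$labels)
  ann_fit <- train_ann(ds, ann_config(epochs = 25L, seed = 5))
  fm <- fit_fusion(list(svm_member(svm_fit, cal), ann_member(ann_fit)), ds$labels,
                   mode = "density_threshold")
  dec <- fusion_classify(fm, ds$values)
  th <- fusion_threshold(fm$priors, fm$theta_i)
  expect_equal(dec$label, as.integer(!(dec$y_avg < th)))
  expect_equal(unique(dec$threshold), th)

  y_avg <- average_density(fm, ds$values)
  tab <- sweep_threshold(fm, ds, grid = c(0, stats::quantile(y_avg, 1:8 / 9), max(y_avg) + 1))
  # threshold 0: everything is target -> no false negatives
  expect_equal(tab$fnr[1], 0)
  # threshold beyond the maximum: everything is outlier -> no false positives
  expect_equal(tab$fpr[nrow(tab)], 0)
  # FNR non-decreasing and FPR non-increasing as the threshold increases
  expect_true(all(diff(tab$fnr) >= -1e-12))
  expect_true(all(diff(tab$fpr) <= 1e-12))
  expect_error(sweep_threshold(fm, ds, numeric(0)), "empty")
})

test_that("classification is deterministic and records all intermediates", {
  ds <- make_std_dataset(60, seed = 47)
  svm_fit <- train_svm(ds, C = 1)
  cal <- fit_platt(decision_value(svm_fit, ds$values), ds$labels)
  fm <- fit_fusion(list(svm_member(svm_fit, cal)), ds$labels)
  d1 <- fusion_classify(fm, ds$values)
  d2 <- fusion_classify(fm, ds$values)
  expect_identical(d1, d2)
  expect_named(d1, c("mu_target", "mu_outlier", "y_avg", "threshold", "label"))
  # priors default to training class frequencies
  expect_equal(fm$priors$p_target, mean(ds$labels == 1L))
})
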