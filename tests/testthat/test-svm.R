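test_that("kernel evaluations match their closed forms", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 0), c(0, 1)), 0)
  x <- rnorm(5)
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 0.7), x, x), 1)
  # polynomial (gamma xz + r)^d by hand: (1*1 + 1)^2 = 4
  expect_equal(kernel_eval(kernel_spec("polynomial", gamma = 1, r = 1, d = 2),
                           c(1, 0), c(1, 0)), 4)
  expect_equal(kernel_eval(kernel_spec("sigmoid", gamma = 0.5, r = -1), c(2, 0), c(1, 0)),
               tanh(0.5 * 2 - 1))
  expect_error(kernel_eval(kernel_spec("linear"), 1:2, 1:3), "dimension")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma")
  # kernel_matrix agrees with elementwise kernel_eval
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(6), 2, 3)
  for (k in list(kernel_spec("rbf", gamma = 0.3), kernel_spec("polynomial", 0.5, 1, 2))) {
    K <- kernel_matrix(k, A, B)
    for (i in 1:4) for (j in 1:2)
      expect_equal(K[i, j], kernel_eval(k, A[i, ], B[j, ]), tolerance = 1e-12)
  }
})

two_point_ds <- function() {
  sc <- feature_schema(data.frame(name = c("X1", "X2"), kind = "real", unit = ""))
  labeled_dataset(rbind(c(0, 0), c(2, 2)), c(0L, 1L), "toy", sc)
}

test_that("max-margin solution on a separable pair puts the midpoint on the hyperplane", {
  m <- train_svm(two_point_ds(), C = 1000, kernel = kernel_spec("linear"))
  expect_equal(decision_value(m, c(1, 1)), 0, tolerance = 1e-6)
  expect_lt(decision_value(m, c(0, 0)), 0)
  expect_gt(decision_value(m, c(2, 2)), 0)
  expect_equal(svm_predict(m, rbind(c(0, 0), c(2, 2))), c(0L, 1L))
})

test_that("RBF kernel separates the XOR pattern", {
  sc <- feature_schema(data.frame(name = c("X1", "X2"), kind = "real", unit = ""))
  xor <- labeled_dataset(rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)),
                         c(0L, 0L, 1L, 1L), "xor", sc)
  m <- train_svm(xor, C = 10, kernel = kernel_spec("rbf", gamma = 1))
  expect_equal(svm_predict(m, xor$values), xor$labels)
})

test_that("trained models satisfy dual feasibility and are row-order invariant", {
  ds <- make_std_dataset(150, separation = 1.5, seed = 21)
  m <- train_svm(ds, C = 2)
  expect_true(all(abs(m$dual_coefs) <= 2 + 1e-6))
  expect_lt(abs(sum(m$dual_coefs)), 1e-6)
  # duplicate of a training point as query reproduces its decision value
  f_all <- decision_value(m, ds$values)
  expect_equal(decision_value(m, ds$values[7, ]), f_all[7], tolerance = 1e-9)
  # permuting training rows leaves the decision function unchanged
  perm <- sample(n_records(ds))
  m2 <- train_svm(subset_rows(ds, perm), C = 2)
  expect_equal(decision_value(m2, ds$values[1:20, ]), f_all[1:20], tolerance = 1e-4)
  # degenerate inputs
  expect_error(train_svm(subset_rows(ds, ds$labels == 0L), C = 1), "both classes")
  expect_error(train_svm(ds, C = -1), "positive")
})

test_that("decision_value is the kernel expansion plus bias", {
  # empty support set: bias only
  empty <- hand_svm_model(matrix(numeric(0), 0, 2), numeric(0), 0.5,
                          kernel_spec("linear"))
  expect_equal(decision_value(empty, c(3, 3)), 0.5)
  # single support vector, a*y = 1, linear kernel, b = 0, query = SV, |SV|^2 = 2
  one <- hand_svm_model(rbind(c(1, 1)), 1, 0, kernel_spec("linear"))
  expect_equal(decision_value(one, c(1, 1)), 2)
  # sign(decision value) defines the prediction
  ds <- make_std_dataset(80, seed = 4)
  m <- train_svm(ds, C = 1)
  q <- matrix(rnorm(100 * 8), 100, 8)
  expect_equal(svm_predict(m, q), as.integer(decision_value(m, q) >= 0))
  expect_error(decision_value(m, 1:3), "dimension")
})

test_that("Platt calibration is monotone, symmetric and prevalence-consistent", {
  # perfectly separated scores
  cal <- fit_platt(c(rep(-1, 20), rep(1, 20)), rep(c(0L, 1L), each = 20))
  expect_gt(platt_posterior(cal, 1), 0.5)
  expect_lt(platt_posterior(cal, -1), 0.5)
  # symmetric scores, balanced labels -> p(0) = 0.5
  cal2 <- fit_platt(c(-2, -1, 1, 2), c(0L, 0L, 1L, 1L))
  expect_equal(platt_posterior(cal2, 0), 0.5, tolerance = 1e-6)
  # labels independent of scores: mean fitted posterior tracks prevalence
  set.seed(8)
  f <- rnorm(500); y <- rbinom(500, 1, 0.3)
  cal3 <- fit_platt(f, y)
  expect_lt(abs(mean(platt_posterior(cal3, f)) - mean(y)), 0.05)
  expect_error(fit_platt(f, rep(1L, 500)), "both classes")
  expect_error(fit_platt(c(1, Inf), c(0L, 1L)), "finite")
})

test_that("calibrated posteriors are valid probabilities monotone in the margin", {
  ds <- make_std_dataset(200, seed = 31)
  m <- train_svm(ds, C = 1)
  cal <- fit_platt(decision_value(m, ds$values), ds$labels)
  f <- sort(decision_value(m, ds$values))
  p <- platt_posterior(cal, f)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) >= 0))
  expect_equal(p + (1 - p), rep(1, length(p)))
  # agrees with the sigmoid formula on hand values
  expect_equal(svm_posterior(m, cal, ds$values[3, ]),
               1 / (1 + exp(cal$A * decision_value(m, ds$values[3, ]) + cal$B)),
               tolerance = 1e-12)
})

test_that("SVM models survive a JSON round trip with calibration", {
  ds <- make_std_dataset(100, seed = 14)
  m <- train_svm(ds, C = 1)
  cal <- fit_platt(decision_value(m, ds$values), ds$labels)
  back <- svm_from_json(svm_to_json(m, cal))
  q <- ds$values[1:10, ]
  expect_equal(decision_value(back$model, q), decision_value(m, q), tolerance = 1e-12)
  expect_equal(back$cal$A, cal$A)
  expect_equal(back$cal$B, cal$B)
})
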