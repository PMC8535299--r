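#' Class priors for the fusion layer
#'
#' Prior probabilities of the target class (diabetic, label 1) and the
#' outlier class (non-diabetic, label 0). They must be strictly inside (0,1)
#' and sum to one.
#'
#' @param p_target prior P(target).
#' @param p_outlier prior P(outlier); default the complement.
#' @return An object of class `class_priors`.
#' @export
class_priors <- function(p_target, p_outlier = 1 - p_target) {
  if (!(p_target > 0 && p_target < 1) || !(p_outlier > 0 && p_outlier < 1))
    stop("priors must lie strictly inside (0, 1)")
  if (abs(p_target + p_outlier - 1) > 1e-9)
    stop("priors must sum to 1")
  structure(list(p_target = p_target, p_outlier = p_outlier), class = "class_priors")
}

#' Posterior of the target class from a fitted member classifier
#'
#' Generic dispatched on the member type; the fusion layer only requires that
#' each member map a feature matrix to P(diabetic | x) in (0, 1).
#'
#' @param member a member classifier (see [svm_member()], [ann_member()]).
#' @param x feature vector or matrix of row vectors.
#' @return posterior probabilities.
#' @export
posterior_target <- function(member, x) UseMethod("posterior_target")

#' SVM member for the fusion layer
#' @param model an [svm_model][train_svm()].
#' @param cal a [fit_platt()] calibration.
#' @return member object usable in [fusion_model()].
#' @export
svm_member <- function(model, cal) {
  stopifnot(inherits(model, "svm_model"), inherits(cal, "platt_calibration"))
  structure(list(model = model, cal = cal), class = c("svm_member", "fusion_member"))
}

#' @export
posterior_target.svm_member <- function(member, x) svm_posterior(member$model, member$cal, x)

#' ANN member for the fusion layer
#' @param model a trained [ann_model()].
#' @return member object usable in [fusion_model()].
#' @export
ann_member <- function(model) {
  stopifnot(inherits(model, "ann_model"))
  structure(list(model = model), class = c("ann_member", "fusion_member"))
}

#' @export
posterior_target.ann_member <- function(member, x) ann_posterior(member$model, x)

#' Fusion of calibrated base classifiers
#'
#' Holds L calibrated members, the class priors, per-member uniform density
#' levels theta_i, a posterior combining rule, and the operating mode:
#' `"mean_posterior"` decides diabetic when the combined target posterior is
#' at least the combined outlier posterior; `"density_threshold"` compares
#' the averaged class-conditional density proxy against the tunable threshold
#' from [fusion_threshold()], declaring an outlier strictly below it.
#'
#' @param members non-empty list of fusion members.
#' @param priors a [class_priors()].
#' @param theta_i positive uniform density level per member (recycled).
#' @param rule posterior combining rule: `"mean"`, `"min"`, `"max"`, `"product"`.
#' @param mode `"mean_posterior"` (default) or `"density_threshold"`.
#' @return An object of class `fusion_model`.
#' @export
fusion_model <- function(members, priors, theta_i = 1,
                         rule = c("mean", "min", "max", "product"),
                         mode = c("mean_posterior", "density_threshold")) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  if (!length(members)) stop("need at least one member classifier")
  for (m in members)
    if (!inherits(m, "fusion_member")) stop("members must be fusion members")
  if (length(theta_i) == 1L) theta_i <- rep(theta_i, length(members))
  if (length(theta_i) != length(members)) stop("theta_i must match member count")
  if (any(theta_i <= 0)) stop("theta_i must be positive")
  stopifnot(inherits(priors, "class_priors"))
  structure(list(members = members, priors = priors, theta_i = theta_i,
                 rule = rule, mode = mode),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("Fusion model:", length(x$members), "members;", x$rule, "rule;",
      x$mode, "mode; P(target) =", x$priors$p_target, "\n")
  invisible(x)
}

#' Member posteriors for the target class
#'
#' Length-L vector (or n x L matrix) of member posteriors P_i(target | x), in
#' member order, clipped to [1e-12, 1 - 1e-12] as a numeric guard.
#'
#' @param fm a [fusion_model()].
#' @param x feature vector or matrix of row vectors.
#' @return numeric matrix, one row per input, one column per member.
#' @export
member_posteriors <- function(fm, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- vapply(fm$members, function(m) posterior_target(m, x), numeric(nrow(x)))
  p <- matrix(p, nrow = nrow(x))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Combine member posteriors by a fusion rule
#'
#' mean averages the L posteriors (the combined posterior mu), min/max take
#' the extrema, product multiplies them.
#'
#' @param posteriors non-empty numeric vector of probabilities.
#' @param rule one of `"mean"`, `"min"`, `"max"`, `"product"`.
#' @return combined scalar.
#' @export
combine_rule <- function(posteriors, rule = c("mean", "min", "max", "product")) {
  rule <- match.arg(rule)
  if (!length(posteriors)) stop("empty posterior sequence")
  switch(rule,
         mean = mean(posteriors),
         min = min(posteriors),
         max = max(posteriors),
         product = prod(posteriors))
}

#' Outlier threshold of the fusion layer
#'
#' \eqn{\bar\theta = \frac{P(outlier)}{P(target)} \cdot \frac1L \sum_i
#' \theta_i}: the prior odds against the target class scaled by the mean
#' uniform density level of the members. Inputs whose averaged density proxy
#' falls strictly below it are declared outliers (non-diabetic); the
#' threshold can be tuned to trade false negatives against false positives.
#'
#' @param priors a [class_priors()].
#' @param theta_i positive density levels, one per member.
#' @return scalar threshold.
#' @export
fusion_threshold <- function(priors, theta_i) {
  stopifnot(inherits(priors, "class_priors"))
  if (any(theta_i <= 0)) stop("theta_i must be positive")
  (priors$p_outlier / priors$p_target) * mean(theta_i)
}

#' Averaged class-conditional density proxy
#'
#' With the shared-evidence simplification P_i(x) ~= P(x), the average of the
#' members' class-conditional densities is proportional to the mean target
#' posterior divided by P(target); the common positive factor P(x) is dropped
#' and absorbed by the tunable threshold.
#'
#' @param fm a [fusion_model()].
#' @param x feature vector or matrix.
#' @return non-negative values, monotone in the mean posterior.
#' @export
average_density <- function(fm, x) {
  p <- member_posteriors(fm, x)
  rowMeans(p) / fm$priors$p_target
}

#' Classify inputs with the fusion layer
#'
#' In `mean_posterior` mode the combined target and outlier posteriors are
#' compared and the input is an outlier only when mu(target|x) is strictly
#' below mu(outlier|x) — ties go to the target class. In `density_threshold`
#' mode the input is an outlier when the averaged density proxy is strictly
#' below the threshold.
#'
#' @param fm a [fusion_model()].
#' @param x feature vector or matrix of row vectors.
#' @param threshold threshold for `density_threshold` mode; default
#'   [fusion_threshold()] of the model's priors and theta_i.
#' @return data.frame of class `fusion_decision` with columns `mu_target`,
#'   `mu_outlier`, `y_avg`, `threshold`, `label`.
#' @export
fusion_classify <- function(fm, x, threshold = fusion_threshold(fm$priors, fm$theta_i)) {
  p <- member_posteriors(fm, x)
  mu_t <- apply(p, 1, combine_rule, rule = fm$rule)
  mu_o <- apply(1 - p, 1, combine_rule, rule = fm$rule)
  y_avg <- rowMeans(p) / fm$priors$p_target
  label <- if (fm$mode == "mean_posterior") {
    as.integer(!(mu_t < mu_o))
  } else {
    as.integer(!(y_avg < threshold))
  }
  out <- data.frame(mu_target = mu_t, mu_outlier = mu_o, y_avg = y_avg,
                    threshold = threshold, label = label)
  class(out) <- c("fusion_decision", "data.frame")
  out
}

#' Sweep the outlier threshold and tabulate the error trade-off
#'
#' For each candidate threshold the labeled data are classified in
#' `density_threshold` mode and the false-positive and false-negative rates
#' recorded. Lowering the threshold can only pull more inputs into the target
#' class, so the FNR is non-increasing and the FPR non-decreasing as the
#' threshold decreases.
#'
#' @param fm a [fusion_model()].
#' @param ds a complete, standardized [labeled_dataset()].
#' @param grid non-empty numeric vector of threshold values.
#' @return data.frame with columns `threshold`, `fpr`, `fnr`.
#' @export
sweep_threshold <- function(fm, ds, grid) {
  if (!length(grid)) stop("empty threshold grid")
  y_avg <- average_density(fm, ds$values)
  truth <- ds$labels
  rows <- lapply(grid, function(th) {
    pred <- as.integer(!(y_avg < th))
    cm <- confusion(truth, pred)
    data.frame(threshold = th,
               fpr = if (cm$TN + cm$FP > 0) cm$FP / (cm$TN + cm$FP) else NA_real_,
               fnr = if (cm$TP + cm$FN > 0) cm$FN / (cm$TP + cm$FN) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Fit a fusion model from trained members and training labels
#'
#' Priors default to the training-set class frequencies; theta_i defaults to
#' one per member.
#'
#' @param members list of fusion members.
#' @param train_labels integer labels of the training fold.
#' @param theta_i density levels (default 1 per member).
#' @param rule,mode passed to [fusion_model()].
#' @return A [fusion_model()].
#' @export
fit_fusion <- function(members, train_labels, theta_i = 1,
                       rule = "mean", mode = "mean_posterior") {
  p1 <- mean(train_labels == 1L)
  fusion_model(members, class_priors(p1), theta_i = theta_i,
               rule = rule, mode = mode)
}
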