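#' Convert encoded zeros to explicit missing values
#'
#' Pima-style tables encode unmeasured values as a literal 0 in features where
#' zero is physiologically impossible (glucose, blood pressure, skinfold,
#' insulin, BMI). For every feature listed in the schema's `zero_is_missing`
#' set, cells equal to zero become `NA`; all other cells are untouched. This
#' is the only place zeros are reinterpreted — parsing never does it.
#'
#' @param ds a [labeled_dataset()].
#' @return A [labeled_dataset()] with encoded zeros marked missing.
#' @export
mark_missing <- function(ds) {
  vals <- ds$values
  for (nm in ds$schema$zero_is_missing) {
    col <- vals[, nm]
    col[!is.na(col) & col == 0] <- NA
    vals[, nm] <- col
  }
  labeled_dataset(vals, ds$labels, ds$sources, ds$schema)
}

#' Fit a mean-imputation model
#'
#' Computes, per feature, the arithmetic mean of the non-missing training
#' cells. Held-out data are later imputed with these training means only, so
#' no test-set information leaks into the statistics.
#'
#' @param train a [labeled_dataset()] (training rows only).
#' @return An object of class `imputation_model`: named vector of per-feature
#'   means.
#' @export
fit_imputer <- function(train) {
  means <- colMeans(train$values, na.rm = TRUE)
  empty <- names(means)[!is.finite(means)]
  if (length(empty))
    stop("feature(s) entirely missing in training data: ",
         paste(empty, collapse = ", "))
  structure(list(means = means, feature_names = colnames(train$values)),
            class = "imputation_model")
}

#' Impute missing cells with training means
#'
#' Missing cells are replaced by the fitted per-feature mean; observed cells
#' pass through unchanged. The output contains no missing cells.
#'
#' @param model an [fit_imputer()] model.
#' @param ds a [labeled_dataset()].
#' @return The imputed [labeled_dataset()].
#' @export
impute <- function(model, ds) {
  stopifnot(identical(colnames(ds$values), model$feature_names))
  vals <- ds$values
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (any(nas)) vals[nas, j] <- model$means[j]
  }
  labeled_dataset(vals, ds$labels, ds$sources, ds$schema)
}

#' Fit a z-score standardization model
#'
#' Per-feature location (mean) and scale (sample standard deviation, n-1
#' denominator) computed on complete training data.
#'
#' @param train a [labeled_dataset()] with no missing cells.
#' @return An object of class `standardization_model`: named `location` and
#'   `scale` vectors.
#' @export
fit_standardizer <- function(train) {
  if (anyNA(train$values)) stop("standardizer requires complete (imputed) data")
  loc <- colMeans(train$values)
  sc <- apply(train$values, 2, stats::sd)
  flat <- names(sc)[!is.finite(sc) | sc <= 0]
  if (length(flat))
    stop("constant feature(s) cannot be standardized: ", paste(flat, collapse = ", "))
  structure(list(location = loc, scale = sc, feature_names = colnames(train$values)),
            class = "standardization_model")
}

#' Apply z-score standardization
#'
#' Every cell becomes (x - location) / scale using the training statistics.
#'
#' @param model a [fit_standardizer()] model.
#' @param ds a [labeled_dataset()] with no missing cells.
#' @return The standardized [labeled_dataset()].
#' @export
standardize <- function(model, ds) {
  if (anyNA(ds$values)) stop("standardize requires complete (imputed) data")
  stopifnot(identical(colnames(ds$values), model$feature_names))
  vals <- sweep(sweep(ds$values, 2, model$location, "-"), 2, model$scale, "/")
  labeled_dataset(vals, ds$labels, ds$sources, ds$schema)
}

#' Invert a z-score standardization
#' @param model a [fit_standardizer()] model.
#' @param ds a standardized [labeled_dataset()].
#' @return The dataset on the original scale.
#' @export
unstandardize <- function(model, ds) {
  vals <- sweep(sweep(ds$values, 2, model$scale, "*"), 2, model$location, "+")
  labeled_dataset(vals, ds$labels, ds$sources, ds$schema)
}

#' Fit imputer + standardizer on training rows and apply to any split
#'
#' Convenience wrapper enforcing the fit-on-train/apply-on-test discipline
#' used throughout cross-validation.
#'
#' @param train training [labeled_dataset()] (already [mark_missing()]-ed).
#' @return list with `imputer`, `standardizer`, and `transform(ds)` closure.
#' @export
fit_preprocessor <- function(train) {
  imp <- fit_imputer(train)
  std <- fit_standardizer(impute(imp, train))
  list(
    imputer = imp,
    standardizer = std,
    transform = function(ds) standardize(std, impute(imp, ds))
  )
}

#' Serialize preprocessing models to JSON
#' @param imputer an [fit_imputer()] model.
#' @param standardizer a [fit_standardizer()] model.
#' @return JSON string mapping each feature to its mean and sd.
#' @export
preprocessing_to_json <- function(imputer, standardizer) {
  obj <- lapply(seq_along(imputer$feature_names), function(j) {
    list(impute_mean = imputer$means[[j]],
         mean = standardizer$location[[j]],
         sd = standardizer$scale[[j]])
  })
  names(obj) <- imputer$feature_names
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}
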