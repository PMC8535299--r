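#' Feature schema for the eight-feature diabetes table
#'
#' A `feature_schema` records the ordered clinical features of the standard
#' diabetes table (glucose, pregnancies, blood pressure, skin thickness,
#' insulin, BMI, pedigree function, age), their kinds (real or integer),
#' units, which features encode missingness as a literal zero, and the name
#' of the binary outcome column.
#'
#' @param features data.frame with columns `name`, `kind` (one of `"real"`,
#'   `"integer"`) and `unit`.
#' @param zero_is_missing character vector of feature names whose zeros are
#'   physiologically impossible and therefore denote missing values.
#' @param label_name name of the outcome column (0 = non-diabetic,
#'   1 = diabetic).
#' @return An object of class `feature_schema`.
#' @seealso [default_schema()] for the standard instance.
#' @export
feature_schema <- function(features, zero_is_missing = character(), label_name = "Outcome") {
  stopifnot(is.data.frame(features), all(c("name", "kind", "unit") %in% names(features)))
  features$name <- as.character(features$name)
  features$kind <- as.character(features$kind)
  features$unit <- as.character(features$unit)
  if (anyDuplicated(features$name) || any(!nzchar(features$name)))
    stop("feature names must be unique and non-empty")
  if (!all(features$kind %in% c("real", "integer")))
    stop("feature kind must be 'real' or 'integer'")
  bad <- setdiff(zero_is_missing, features$name)
  if (length(bad))
    stop("zero_is_missing names not in schema: ", paste(bad, collapse = ", "))
  structure(
    list(features = features, zero_is_missing = as.character(zero_is_missing),
         label_name = as.character(label_name)),
    class = "feature_schema"
  )
}

#' Default eight-feature diabetes schema
#'
#' The standard feature set shared by the NHANES-derived and Pima-style
#' diabetes tables: plasma glucose at 2 h, number of pregnancies, diastolic
#' blood pressure, triceps skinfold thickness, 2-h serum insulin, body mass
#' index, diabetes pedigree function, and age in years. By default the five
#' features for which a zero is physiologically impossible under the Pima
#' encoding (Glucose, Blood Pressure, Skin Thickness, Insulin, BMI) are
#' flagged `zero_is_missing`; zero pregnancies, pedigree and age zeros are
#' taken at face value.
#'
#' @param zero_is_missing feature names whose zeros denote missing values.
#' @param label_name outcome column name (default `"Outcome"`).
#' @return A [feature_schema()].
#' @examples
#' sc <- default_schema()
#' sc$features$name
#' @export
default_schema <- function(zero_is_missing = c("Glucose", "BloodPressure",
                                               "SkinThickness", "Insulin", "BMI"),
                           label_name = "Outcome") {
  feats <- data.frame(
    name = c("Glucose", "Pregnancies", "BloodPressure", "SkinThickness",
             "Insulin", "BMI", "DiabetesPedigreeFunction", "Age"),
    kind = c("real", "integer", "real", "real", "real", "real", "real", "integer"),
    unit = c("mg/dL (2-h OGTT)", "count", "mm Hg", "mm", "mu U/mL",
             "kg/m^2", "score", "years"),
    stringsAsFactors = FALSE
  )
  feature_schema(feats, zero_is_missing = zero_is_missing, label_name = label_name)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema:", nrow(x$features), "features; label:", x$label_name, "\n")
  print(x$features, row.names = FALSE)
  cat("zero-is-missing:", paste(x$zero_is_missing, collapse = ", "), "\n")
  invisible(x)
}

#' Labeled dataset container
#'
#' Bundles an n x d numeric feature matrix (with `NA` marking missing cells),
#' a binary outcome vector, per-record source tags, and the governing
#' [feature_schema()].
#'
#' @param values numeric matrix, one column per schema feature.
#' @param labels integer vector over {0, 1} (0 = non-diabetic, 1 = diabetic).
#' @param sources character vector of source identifiers, recycled if length 1.
#' @param schema a [feature_schema()].
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(values, labels, sources = "unknown", schema = default_schema()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- NULL
  d <- nrow(schema$features)
  if (ncol(values) != d)
    stop("values has ", ncol(values), " columns; schema declares ", d, " features")
  colnames(values) <- schema$features$name
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels length must equal number of rows")
  bad <- which(!(labels %in% c(0L, 1L)))
  if (length(bad))
    stop("label outside {0,1} at row ", bad[1])
  if (length(sources) == 1L) sources <- rep(sources, nrow(values))
  if (length(sources) != nrow(values))
    stop("sources length must equal number of rows")
  structure(
    list(values = values, labels = labels, sources = as.character(sources), schema = schema),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$values), "records x", ncol(x$values), "features;",
      sum(is.na(x$values)), "missing cells\n")
  cat("sources:", paste(names(table(x$sources)), table(x$sources), sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Number of records in a labeled dataset
#' @param ds a [labeled_dataset()].
#' @return integer record count.
#' @export
n_records <- function(ds) nrow(ds$values)

#' Subset the rows of a labeled dataset
#' @param ds a [labeled_dataset()].
#' @param idx integer or logical row index.
#' @return A [labeled_dataset()] with the selected rows.
#' @export
subset_rows <- function(ds, idx) {
  labeled_dataset(ds$values[idx, , drop = FALSE], ds$labels[idx],
                  ds$sources[idx], ds$schema)
}

#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: ties go away from
#' zero rather than to the even digit.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a labeled dataset from CSV
#'
#' Expects a comma-delimited file with a header naming every schema feature
#' plus the outcome column. Non-numeric or empty feature cells become missing
#' (`NA`); zeros are kept as zeros (zero-to-missing conversion is the job of
#' [mark_missing()], never of the parser). An optional `Source` column carries
#' per-record source tags.
#'
#' @param path CSV file path.
#' @param schema a [feature_schema()].
#' @param source source tag used when the file has no `Source` column
#'   (default: the file name).
#' @return A [labeled_dataset()].
#' @export
read_table <- function(path, schema = default_schema(),
                       source = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c(schema$features$name, schema$label_name)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("input is missing required column(s): ", paste(miss, collapse = ", "))
  vals <- sapply(schema$features$name, function(nm) {
    cell <- trimws(df[[nm]])
    cell[!nzchar(cell)] <- NA_character_
    suppressWarnings(as.numeric(cell))
  })
  if (nrow(df) == 0L) vals <- matrix(numeric(0), 0, nrow(schema$features))
  if (nrow(df) == 1L) vals <- matrix(vals, 1)
  lab_chr <- trimws(df[[schema$label_name]])
  lab <- suppressWarnings(as.integer(lab_chr))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad))
    stop("label value '", lab_chr[bad[1]], "' outside {0,1} at row ", bad[1])
  src <- if ("Source" %in% names(df)) df[["Source"]] else rep(source, nrow(df))
  labeled_dataset(vals, lab, src, schema)
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [read_table()]: features in schema order, the outcome column,
#' and a `Source` column. Missing cells are written as empty strings.
#'
#' @param ds a [labeled_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path) {
  df <- as.data.frame(ds$values)
  df[[ds$schema$label_name]] <- ds$labels
  df$Source <- ds$sources
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Class composition of a labeled dataset
#'
#' Counts and two-decimal percentages per outcome class, the summary used to
#' report dataset composition (e.g. a 10,627-record fused set splitting
#' 66.54/33.46 between non-diabetic and diabetic records). Percentages are
#' rounded half away from zero.
#'
#' @param ds a [labeled_dataset()].
#' @return A list of class `class_summary` with `n_total`, `n_per_class`
#'   (named "0", "1") and `pct_per_class`.
#' @export
class_summary <- function(ds) {
  n <- n_records(ds)
  if (n < 1L) stop("cannot summarize an empty dataset")
  n0 <- sum(ds$labels == 0L)
  n1 <- n - n0
  cnt <- c("0" = n0, "1" = n1)
  structure(
    list(n_total = n, n_per_class = cnt,
         pct_per_class = round_half_away(100 * cnt / n, 2)),
    class = "class_summary"
  )
}

#' @export
print.class_summary <- function(x, ...) {
  cat("n =", x$n_total, "records\n")
  cat(sprintf("  class 0 (non-diabetic): %d (%.2f%%)\n",
              x$n_per_class[["0"]], x$pct_per_class[["0"]]))
  cat(sprintf("  class 1 (diabetic):     %d (%.2f%%)\n",
              x$n_per_class[["1"]], x$pct_per_class[["1"]]))
  invisible(x)
}
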