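#' Binary confusion matrix
#'
#' Tallies true/false positives and negatives with class 1 (diabetic) as the
#' positive class.
#'
#' @param truth integer vector over {0, 1}.
#' @param pred integer vector over {0, 1}, same length.
#' @return An object of class `confusion_matrix` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (!length(truth)) stop("cannot tabulate an empty prediction set")
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L)))
    stop("labels must lie in {0,1}")
  structure(list(TP = sum(truth == 1L & pred == 1L),
                 TN = sum(truth == 0L & pred == 0L),
                 FP = sum(truth == 0L & pred == 1L),
                 FN = sum(truth == 1L & pred == 0L)),
            class = "confusion_matrix")
}

#' Make a confusion matrix from explicit counts
#' @param TP,TN,FP,FN non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  cnt <- c(TP, TN, FP, FN)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Evaluation metrics from a confusion matrix
#'
#' The standard seven-entry evaluation matrix:
#' accuracy = (TP+TN)/n x 100, miss rate = (FP+FN)/n x 100,
#' sensitivity (recall) = TP/(TP+FN) x 100, specificity = TN/(TN+FP) x 100,
#' precision = TP/(TP+FP) x 100, FPR = 1 - specificity/100 and
#' FNR = 1 - sensitivity/100 (proportions). Values are kept at full precision;
#' rounding (half away from zero, 2 decimals) happens only at presentation.
#' A ratio with a zero denominator is reported as `NA` with a warning, never
#' silently as zero.
#'
#' @param cm a [confusion()] matrix.
#' @return An object of class `metrics_report` (named list of the seven
#'   metrics, plus `n`).
#' @export
metrics <- function(cm) {
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, ": zero denominator")
      return(NA_real_)
    }
    num / den
  }
  sens <- 100 * ratio(cm$TP, cm$TP + cm$FN, "sensitivity")
  spec <- 100 * ratio(cm$TN, cm$TN + cm$FP, "specificity")
  structure(list(
    accuracy = 100 * (cm$TP + cm$TN) / n,
    miss_rate = 100 * (cm$FP + cm$FN) / n,
    sensitivity = sens,
    specificity = spec,
    precision = 100 * ratio(cm$TP, cm$TP + cm$FP, "precision"),
    fpr = 1 - spec / 100,
    fnr = 1 - sens / 100,
    n = n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f%%", round_half_away(v, 2)))
  prop <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", round_half_away(v, 2)))
  cat(sprintf("Accuracy      %s\n", pct(x$accuracy)))
  cat(sprintf("Specificity   %s\n", pct(x$specificity)))
  cat(sprintf("Sensitivity   %s\n", pct(x$sensitivity)))
  cat(sprintf("Precision     %s\n", pct(x$precision)))
  cat(sprintf("Miss rate     %s\n", pct(x$miss_rate)))
  cat(sprintf("FPR           %s\n", prop(x$fpr)))
  cat(sprintf("FNR           %s\n", prop(x$fnr)))
  invisible(x)
}

.metric_names <- c("accuracy", "miss_rate", "sensitivity", "specificity",
                   "precision", "fpr", "fnr")

#' Per-metric margins between two reports
#'
#' Differences a - b in percentage points for the percentage metrics and in
#' raw proportion for FPR/FNR; e.g. a fused model at 94.67% accuracy against
#' a standalone one at 88.30% gives a +6.37-point margin.
#'
#' @param a,b [metrics()] reports.
#' @return data.frame with columns `metric`, `a`, `b`, `margin`.
#' @export
compare_reports <- function(a, b) {
  data.frame(metric = .metric_names,
             a = unlist(a[.metric_names]),
             b = unlist(b[.metric_names]),
             margin = unlist(a[.metric_names]) - unlist(b[.metric_names]),
             row.names = NULL)
}

#' Aligned-text table of reports for several classifiers
#' @param reports named list of [metrics()] reports (e.g. SVM, ANN, fusion).
#' @return character vector of table lines (also printed).
#' @export
metrics_table <- function(reports) {
  labels <- c(accuracy = "Accuracy", specificity = "Specificity",
              sensitivity = "Sensitivity", precision = "Precision",
              miss_rate = "Miss rate", fpr = "False Positive Ratio (FPR)",
              fnr = "False Negative Ratio (FNR)")
  fmt <- function(m, v) {
    if (is.na(v)) return("NA")
    if (m %in% c("fpr", "fnr")) sprintf("%.2f", round_half_away(v, 2))
    else sprintf("%.2f%%", round_half_away(v, 2))
  }
  header <- sprintf("%-28s %s", "Evaluation Matrix",
                    paste(sprintf("%12s", names(reports)), collapse = " "))
  lines <- vapply(names(labels), function(m) {
    sprintf("%-28s %s", labels[[m]],
            paste(sprintf("%12s", vapply(reports, function(r) fmt(m, r[[m]]), "")),
                  collapse = " "))
  }, "")
  out <- c(header, lines)
  cat(out, sep = "\n")
  invisible(out)
}

#' Report metrics as a JSON string
#' @param report a [metrics()] report.
#' @return JSON string.
#' @export
metrics_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
}
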