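#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_names Class universe; defaults to the sorted union of the
#'   observed labels.  Any label outside it is an error.
#' @return A `confusion_matrix`: integer K x K matrix with class-name
#'   dimnames.
#' @export
confusion <- function(true_labels, predicted_labels, class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  if (is.null(class_names)) {
    class_names <- sort(unique(c(as.character(true_labels),
                                 as.character(predicted_labels))))
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(true_labels, levels = class_names),
              factor(predicted_labels, levels = class_names))
  out <- matrix(as.integer(cm), nrow = length(class_names),
                dimnames = list(true = class_names,
                                predicted = class_names))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Accuracy, macro precision and macro specificity from a confusion matrix
#'
#' Multiclass metrics via one-vs-rest reduction.  For class `k`:
#' `TP = counts[k, k]`, `FP = colsum_k - TP`, `FN = rowsum_k - TP`,
#' `TN = total - TP - FP - FN`; `precision_k = TP / (TP + FP)` and
#' `specificity_k = TN / (TN + FP)`.  Reported values are percentages:
#' accuracy is `100 * trace / total`; precision and specificity are
#' macro (unweighted) means over classes.  A class never predicted
#' (`TP + FP = 0`) is excluded from the precision macro mean with a
#' message.
#'
#' @param cm A [confusion()] matrix.
#' @return A `metrics_report`: list with `accuracy`, `precision`,
#'   `specificity` (percent) and a `per_class` data.frame of
#'   TP/FP/FN/TN and per-class rates.
#' @export
metrics <- function(cm) {
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- total - tp - fp - fn
  precision_k <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  specificity_k <- tn / (tn + fp)
  if (anyNA(precision_k)) {
    message("class(es) never predicted, excluded from macro precision: ",
            paste(rownames(counts)[is.na(precision_k)], collapse = ", "))
  }
  structure(
    list(accuracy = 100 * sum(tp) / total,
         precision = 100 * mean(precision_k, na.rm = TRUE),
         specificity = 100 * mean(specificity_k),
         per_class = data.frame(class = rownames(counts),
                                TP = tp, FP = fp, FN = fn, TN = tn,
                                precision = 100 * precision_k,
                                specificity = 100 * specificity_k,
                                row.names = NULL)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  specificity %.2f%% (macro)\n",
              x$accuracy, x$precision, x$specificity))
  invisible(x)
}

#' Round half up to a number of decimals
#'
#' Reporting convention for percentage tables (R's `round` rounds half
#' to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Dimensionality reduction and accuracy improvement of a selected model
#'
#' `reduction_pct = 100 * (n_full - n_selected) / n_full` and
#' `accuracy_improvement_pct = 100 * (acc_selected - acc_full) /
#' acc_full` (relative improvement), both rounded half-up to 2 decimals;
#' `accuracy_delta` is the absolute accuracy difference in percentage
#' points.
#'
#' @param full_report,selected_report [metrics()] reports, or bare
#'   accuracy percentages.
#' @param n_full,n_selected Wavelength counts before/after selection.
#' @return List with `reduction_pct`, `accuracy_improvement_pct`,
#'   `accuracy_delta`.
#' @export
improvement_stats <- function(full_report, selected_report,
                              n_full, n_selected) {
  if (n_selected > n_full) stop("n_selected must be <= n_full")
  acc_full <- if (inherits(full_report, "metrics_report")) {
    full_report$accuracy
  } else {
    as.numeric(full_report)
  }
  acc_sel <- if (inherits(selected_report, "metrics_report")) {
    selected_report$accuracy
  } else {
    as.numeric(selected_report)
  }
  list(reduction_pct =
         round_half_up(100 * (n_full - n_selected) / n_full, 2),
       accuracy_improvement_pct =
         round_half_up(100 * (acc_sel - acc_full) / acc_full, 2),
       accuracy_delta = round_half_up(acc_sel - acc_full, 2))
}
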