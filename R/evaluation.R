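# Thematic-accuracy assessment: confusion matrix, overall / producer's (map)
# / user's accuracy, and the kappa coefficient. Orientation is fixed:
# rows = predicted class, columns = true class.

#' Confusion matrix of predicted vs true labels
#'
#' `counts[r, v]` is the number of objects predicted as class `r` that truly
#' belong to class `v` (rows = predicted, columns = true).
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param label_order class order; defaults to the sorted union of labels.
#'   Labels outside `label_order` are an error.
#' @return an integer matrix of class `confusion_matrix` with dimnames
#'   `predicted` x `true`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             label_order = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label sequences must have equal length")
  if (is.null(label_order))
    label_order <- sort(unique(c(true_labels, predicted_labels)))
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), label_order)
  if (length(unknown)) stop("unknown label(s): ",
                            paste(unknown, collapse = ", "))
  p <- factor(predicted_labels, levels = label_order)
  t <- factor(true_labels, levels = label_order)
  m <- table(predicted = p, true = t)
  cm <- matrix(as.integer(m), nrow = length(label_order),
               dimnames = list(predicted = label_order, true = label_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

as_cm <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0), sum(cm) >= 1)
  cm
}

#' Overall accuracy
#'
#' The standard definition `sum(diag) / T`. The source formulation also
#' prints a variant that subtracts `sum(diag) / c` (with `c` the class
#' count); that variant cannot reach the accuracies reported alongside it and
#' is treated as a typographical artifact, but it remains available with
#' `printed_variant = TRUE` for auditability.
#'
#' @param cm a [confusion_matrix()].
#' @param printed_variant evaluate the printed (non-standard) variant.
#' @return overall accuracy in `[0, 1]` (printed variant may be negative).
#' @export
overall_accuracy <- function(cm, printed_variant = FALSE) {
  cm <- as_cm(cm)
  oa <- sum(diag(cm)) / sum(cm)
  if (printed_variant) oa - sum(diag(cm)) / nrow(cm) else oa
}

#' Producer's (map) accuracy of one class
#'
#' Correctly classified objects of class `r` over the true-class-`r` column
#' total. `NA` when the class never truly occurs.
#'
#' @param cm a [confusion_matrix()].
#' @param class_r class name or index; `NULL` returns all classes.
#' @return producer's accuracy (or a named vector over classes).
#' @export
map_accuracy <- function(cm, class_r = NULL) {
  m <- as_cm(cm)
  per <- diag(m) / colSums(m)
  per[colSums(m) == 0] <- NA_real_
  names(per) <- colnames(m)
  if (is.null(class_r)) per else unname(per[class_r])
}

#' User's accuracy of one class
#'
#' Correctly classified objects of class `r` over the predicted-`r` row
#' total. `NA` when the class is never predicted.
#'
#' @inheritParams map_accuracy
#' @return user's accuracy (or a named vector over classes).
#' @export
user_accuracy <- function(cm, class_r = NULL) {
  m <- as_cm(cm)
  per <- diag(m) / rowSums(m)
  per[rowSums(m) == 0] <- NA_real_
  names(per) <- rownames(m)
  if (is.null(class_r)) per else unname(per[class_r])
}

#' Kappa coefficient
#'
#' Chance-corrected agreement
#' `(T sum(diag) - sum(row_g col_g)) / (T^2 - sum(row_g col_g))`
#' over the confusion matrix's row and column totals. `NA` when the
#' denominator is zero (all mass in one row-column pair).
#'
#' @param cm a [confusion_matrix()].
#' @return kappa in `[-1, 1]`, or `NA`.
#' @export
kappa_coefficient <- function(cm) {
  m <- as_cm(cm)
  T <- sum(m)
  chance <- sum(rowSums(m) * colSums(m))
  den <- T^2 - chance
  if (den == 0) return(NA_real_)
  (T * sum(diag(m)) - chance) / den
}

#' Full thematic-accuracy report
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `accuracy_report` with `overall_accuracy`,
#'   per-class `map_accuracy` and `user_accuracy`, `kappa`, `n` and the
#'   matrix itself.
#' @export
accuracy_report <- function(cm) {
  structure(list(overall_accuracy = overall_accuracy(cm),
                 map_accuracy = map_accuracy(cm),
                 user_accuracy = user_accuracy(cm),
                 kappa = kappa_coefficient(cm),
                 n = sum(as_cm(cm)),
                 confusion = unclass(cm)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Thematic accuracy report\n")
  cat(sprintf("  n = %d, overall accuracy = %.4f, kappa = %.4f\n",
              x$n, x$overall_accuracy, x$kappa))
  for (cl in names(x$map_accuracy))
    cat(sprintf("  %-12s producer's = %s  user's = %s\n", cl,
                format(round(x$map_accuracy[cl], 4)),
                format(round(x$user_accuracy[cl], 4))))
  cat("Confusion matrix (rows = predicted, cols = true):\n")
  print(x$confusion)
  invisible(x)
}
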