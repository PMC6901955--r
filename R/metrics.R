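#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.  The class list is the
#' set of classes observed in the true labels; predicting a class absent
#' from the truth is an error.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Optional explicit class list (superset of both).
#' @return Integer matrix of counts, true x predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  check_label_pair(truth, predicted)
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  extra <- setdiff(unique(predicted), classes)
  if (length(extra))
    stop("predicted class not present in the true labels: ", extra[1L])
  table(factor(truth, classes), factor(predicted, classes),
        dnn = c("truth", "predicted"))
}

check_label_pair <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty label vectors")
  if (length(truth) != length(predicted))
    stop("label vectors differ in length (", length(truth), " vs ",
         length(predicted), ")")
}

#' Multi-class Matthews correlation coefficient (Gorodkin)
#'
#' Generalizes the Matthews correlation to K classes as
#' `cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))`, where X and Y are the n x K 0-1
#' indicator matrices of the predicted and true classes and cov(.,.) is the
#' mean over classes of the sample covariance of the paired indicator
#' columns.  Equivalently, from the confusion matrix C with total n,
#' row sums t (truth) and column sums p (prediction):
#' `(n * trace(C) - sum(t * p)) / sqrt((n^2 - sum(p^2)) (n^2 - sum(t^2)))`.
#' Degenerate cases where either variance term vanishes (e.g. every sample
#' predicted as one class) score 0.  For K = 2 this reduces to the classical
#' binary MCC.
#'
#' @inheritParams confusion_matrix
#' @return A score in \[-1, 1\].
#' @export
multiclass_mcc <- function(truth, predicted, classes = NULL) {
  C <- confusion_matrix(truth, predicted, classes)
  mcc_from_confusion(C)
}

mcc_from_confusion <- function(C) {
  C <- unclass(as.matrix(C))
  n <- sum(C)
  tk <- rowSums(C)
  pk <- colSums(C)
  num <- n * sum(diag(C)) - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluate predictions against true labels
#'
#' @inheritParams confusion_matrix
#' @return An `evaluation_report`: list with `confusion` (true x predicted
#'   counts), `per_class_accuracy` (recall per class), `accuracy` (overall)
#'   and `mcc` (multi-class Matthews correlation).
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  C <- confusion_matrix(truth, predicted, classes)
  per_class <- diag(C) / rowSums(C)
  structure(list(confusion = C,
                 per_class_accuracy = per_class,
                 accuracy = sum(diag(C)) / sum(C),
                 mcc = mcc_from_confusion(C)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.4f, MCC %.4f (%d samples, %d classes)\n",
              x$accuracy, x$mcc, sum(x$confusion), nrow(x$confusion)))
  invisible(x)
}

#' Balanced (weighted) accuracy from a confusion matrix
#'
#' Mean of the per-class recalls over the classes with at least one true
#' sample; 1.0 for a diagonal confusion.  This is the per-tree accuracy
#' weight used inside Monte Carlo feature selection.
#'
#' @param confusion Square count matrix, rows = true classes.
#' @return Fraction in \[0, 1\].
#' @export
weighted_accuracy <- function(confusion) {
  C <- unclass(as.matrix(confusion))
  if (length(C) == 0L || sum(C) == 0) stop("empty confusion matrix")
  have <- rowSums(C) > 0
  mean((diag(C) / rowSums(C))[have])
}
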