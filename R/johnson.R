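#' Johnson reducer over a discrete decision table
#'
#' Greedy rough-set attribute reduction: repeatedly pick the feature that
#' discerns the largest number of not-yet-discerned between-class sample
#' pairs, until every discernible pair is covered.  Pairs no feature can
#' discern are ignored.  Count ties break on the lexicographically smaller
#' feature identifier, so the reduct is deterministic.
#'
#' @param D Matrix of discrete codes, samples x features, with feature
#'   column names.
#' @param labels Class label per sample.
#' @return Character vector of selected feature ids (a subset of the
#'   columns), empty when no between-class pair is discernible.
#' @export
johnson_reduce_discrete <- function(D, labels) {
  stopifnot(is.matrix(D))
  if (ncol(D) == 0L) stop("empty feature set")
  labels <- as.character(labels)
  n <- nrow(D)
  pairs <- which(outer(labels, labels, "!=") & upper.tri(diag(n)),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(character(0))
  neq <- D[pairs[, 1L], , drop = FALSE] != D[pairs[, 2L], , drop = FALSE]
  uncovered <- rowSums(neq) > 0          # drop indiscernible pairs
  ord_ids <- colnames(D)
  picked <- character(0)
  while (any(uncovered)) {
    counts <- colSums(neq[uncovered, , drop = FALSE])
    best <- order(-counts, ord_ids)[1L]
    if (counts[best] == 0L) break
    picked <- c(picked, ord_ids[best])
    uncovered <- uncovered & !neq[, best]
  }
  picked
}

#' Johnson reducer over informative features of an expression matrix
#'
#' Discretizes each feature with supervised MDL binning
#' ([mdl_discretize()]) and runs the greedy Johnson reduction on the
#' resulting decision table.  The reduct keeps a small attribute subset with
#' classification ability similar to the full informative set.
#'
#' @param em A fully imputed [expression_matrix()].
#' @param features Informative feature ids (non-empty, present in `em`).
#' @return Character vector of reduct feature ids.
#' @export
johnson_reduce <- function(em, features) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(features) == 0L) stop("empty feature set")
  unknown <- setdiff(features, feature_ids(em))
  if (length(unknown)) stop("unknown feature: ", unknown[1L])
  labels <- as.character(em$labels)
  D <- vapply(features, function(f) {
    x <- em$values[, f]
    apply_cuts(x, mdl_discretize(x, labels))
  }, integer(nrow(em$values)))
  D <- matrix(D, nrow = nrow(em$values),
              dimnames = list(NULL, features))
  johnson_reduce_discrete(D, labels)
}
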