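#' Labeled expression matrix
#'
#' Container for a samples x features intensity table with one class label
#' per sample.  Values are positive peptide-binding intensities; missing
#' entries are `NA` until imputed (see [impute_missing_knn()]).
#'
#' @param values Numeric matrix, samples in rows, features (peptides) in
#'   columns.  Row names are sample identifiers, column names feature
#'   identifiers; both must be unique.
#' @param labels Class label per sample (character or factor, length
#'   `nrow(values)`), all non-empty.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (numeric matrix) and `labels` (factor aligned with the rows).
#' @examples
#' v <- matrix(rlnorm(12), 4, 3,
#'             dimnames = list(paste0("S", 1:4), paste0("P", 1:3)))
#' em <- expression_matrix(v, c("A", "A", "B", "B"))
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate sample identifier: ", dup[1L])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate feature identifier: ", dup[1L])
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("need exactly one label per sample (", nrow(values), " samples, ",
         length(labels), " labels)")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("missing label for sample ",
         rownames(values)[which(is.na(labels) | !nzchar(labels))[1L]])
  structure(list(values = values, labels = factor(labels)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " samples x ",
      ncol(x$values), " features, ", nlevels(x$labels), " classes",
      if (anyNA(x$values)) sprintf(", %d missing values",
                                   sum(is.na(x$values))) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' Restrict an expression matrix to a sample and/or feature subset
#'
#' @param x An `expression_matrix`.
#' @param samples,features Identifiers (or indices) to keep; `NULL` keeps all.
#' @return An `expression_matrix` on the requested subset.
#' @export
subset_matrix <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  lab <- as.character(x$labels)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(v))
      if (length(missing)) stop("unknown sample: ", missing[1L])
    }
    v <- v[samples, , drop = FALSE]
    lab <- lab[if (is.character(samples)) match(samples, sample_ids(x)) else samples]
  }
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, colnames(v))
      if (length(missing)) stop("unknown feature: ", missing[1L])
    }
    v <- v[, features, drop = FALSE]
  }
  expression_matrix(v, lab)
}

# shortest decimal strings that survive an as.numeric round trip
format_roundtrip <- function(x) {
  out <- as.character(x)
  bad <- which(is.finite(x) & (is.na(suppressWarnings(as.numeric(out))) |
                                 suppressWarnings(as.numeric(out)) != x))
  for (i in bad) {
    for (d in 16:17) {
      s <- formatC(x[i], digits = d, format = "g")
      if (as.numeric(s) == x[i]) { out[i] <- s; break }
    }
  }
  out
}
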