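#' Read a labeled expression table from delimited text
#'
#' Parses a TSV/CSV intensity table into an [expression_matrix()].  With
#' `orientation = "samples"` (the default) samples are rows: the first column
#' holds sample identifiers, one column holds the class label (by default the
#' last column) and every other column is a feature.  With
#' `orientation = "features"` features are rows, samples are columns, and the
#' labels come from a separate two-column (sample, label) file.
#'
#' Empty cells and the tokens `NA` / `NaN` (case-insensitive) are read as
#' missing values, never as zero.
#'
#' @param path Path to the delimited table (tab- or comma-separated; the
#'   separator is auto-detected from the extension and the header line unless
#'   `sep` is given).
#' @param label_column Name of the label column (samples-as-rows); default
#'   the last column.
#' @param orientation `"samples"` (samples as rows) or `"features"`.
#' @param label_file Two-column delimited file (sample id, label), required
#'   when `orientation = "features"`.
#' @param sep Field separator; `NULL` to auto-detect.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, label_column = NULL,
                                  orientation = c("samples", "features"),
                                  label_file = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("table needs an identifier column plus data")
  ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]

  if (orientation == "samples") {
    if (is.null(label_column)) label_column <- colnames(body)[ncol(body)]
    if (!label_column %in% colnames(body))
      stop("label column '", label_column, "' not found")
    labels <- body[[label_column]]
    if (anyNA(labels) || any(!nzchar(labels)))
      stop("missing label for sample ",
           ids[which(is.na(labels) | !nzchar(labels))[1L]])
    body <- body[, setdiff(colnames(body), label_column), drop = FALSE]
    values <- parse_numeric_block(body, ids, colnames(body))
    expression_matrix(values, labels)
  } else {
    if (is.null(label_file))
      stop("`label_file` is required for features-as-rows tables")
    values <- t(parse_numeric_block(body, ids, colnames(body)))
    lab_tab <- read.table(label_file, header = TRUE, sep = sniff_sep(label_file),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
    idx <- match(rownames(values), lab_tab[[1L]])
    if (anyNA(idx))
      stop("missing label for sample ", rownames(values)[which(is.na(idx))[1L]])
    expression_matrix(values, lab_tab[[2L]][idx])
  }
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    line <- readLines(path, n = 1L)
    if (!grepl("\t", line) && grepl(",", line)) return(",")
    return("\t")
  }
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

parse_numeric_block <- function(body, row_ids, col_ids) {
  mat <- as.matrix(body)
  miss <- is.na(mat) | !nzchar(mat) | toupper(mat) %in% c("NA", "NAN")
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad <- which(is.na(num) & !miss, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d (%s), column %d (%s)",
                 mat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 row_ids[bad[1L, 1L]], bad[1L, 2L], col_ids[bad[1L, 2L]]))
  }
  num[miss] <- NA_real_
  dimnames(num) <- list(row_ids, col_ids)
  num
}

#' Write a labeled expression table
#'
#' Inverse of [read_expression_table()] for the samples-as-rows orientation:
#' first column `sample`, then one column per feature, last column `label`.
#' Intensities are printed with enough digits to round-trip exactly.
#'
#' @param m An [expression_matrix()].
#' @param path Output path (`.csv` writes comma-separated, otherwise tabs).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- matrix(format_roundtrip(m$values), nrow = nrow(m$values))
  chr[is.na(m$values)] <- "NA"
  out <- data.frame(sample = sample_ids(m), chr,
                    label = as.character(m$labels),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("sample", feature_ids(m), "label")
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' Replaces each missing entry (sample s, feature g) by the unweighted mean
#' of the values at s of the `k` features nearest to g.  Nearness is the
#' Euclidean distance between feature profiles computed over samples where
#' both features are observed, with the squared distance rescaled by
#' (total samples / co-observed samples) so sparsity does not shrink
#' distances.  Only features observed at s are candidate neighbours; if fewer
#' than `k` exist all available ones are used, and a feature with no usable
#' neighbour at s falls back to its own observed mean.
#'
#' @param m An [expression_matrix()], possibly with `NA` entries.
#' @param k Number of neighbouring features to average (default 10).
#' @return An [expression_matrix()] with no missing values; observed entries
#'   are untouched, so the operation is idempotent.
#' @export
impute_missing_knn <- function(m, k = 10) {
  stopifnot(inherits(m, "expression_matrix"))
  if (k < 1) stop("`k` must be >= 1")
  V <- m$values
  n <- nrow(V); M <- ncol(V)
  miss <- is.na(V)
  if (!any(miss)) return(m)
  if (k > M - 1L)
    stop("k = ", k, " exceeds the ", M - 1L, " candidate neighbour features")
  all_missing <- colSums(miss) == n
  if (any(all_missing))
    stop("feature missing in all samples: ", colnames(V)[which(all_missing)[1L]])

  obs <- !miss
  A <- V
  A[miss] <- 0
  out <- V
  ord_ids <- colnames(V)
  for (g in which(colSums(miss) > 0L)) {
    co <- as.vector(crossprod(obs, obs[, g]))        # co-observed counts
    d2 <- colSums((A[, g] - A)^2 * (obs[, g] & obs))
    d2 <- d2 * n / pmax(co, 1L)
    d2[co == 0L] <- Inf
    d2[g] <- Inf
    nb_order <- order(d2, ord_ids)
    nb_order <- nb_order[is.finite(d2[nb_order])]
    for (s in which(miss[, g])) {
      cand <- nb_order[obs[s, nb_order]]
      if (length(cand) == 0L) {
        out[s, g] <- mean(V[obs[, g], g])
      } else {
        use <- cand[seq_len(min(k, length(cand)))]
        out[s, g] <- mean(V[s, use])
      }
    }
  }
  expression_matrix(out, as.character(m$labels))
}
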