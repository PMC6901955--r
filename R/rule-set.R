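#' Ordered threshold rule sets
#'
#' A `rule_set` is an ordered list of conjunctive threshold rules plus a
#' default class: the first rule whose conditions all hold classifies a
#' sample, and samples matching no rule get the default class, so
#' classification is total.  Conditions compare one feature's intensity to a
#' threshold with `<=` or `>=`, e.g.
#' `IF Peptide1<=0.7 AND Peptide2>=1.02 THEN type = "Brain cancer"`.
#'
#' @param rules List of rules, each a list with elements `conditions` (a
#'   data frame with columns `feature`, `op` in `c("<=", ">=")`, `threshold`)
#'   and `class`.
#' @param default_class Class assigned when no rule fires.
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(rules = list(), default_class) {
  if (missing(default_class) || !nzchar(default_class))
    stop("`default_class` must be a non-empty class label")
  rules <- lapply(rules, function(r) {
    rownames(r$conditions) <- NULL
    r
  })
  for (r in rules) {
    stopifnot(is.list(r), !is.null(r$class), nzchar(r$class))
    cd <- r$conditions
    stopifnot(is.data.frame(cd),
              all(c("feature", "op", "threshold") %in% names(cd)))
    if (!all(cd$op %in% c("<=", ">=")))
      stop("rule operators must be <= or >=")
    if (any(!is.finite(cd$threshold)))
      stop("rule thresholds must be finite")
    if (anyDuplicated(paste(cd$feature, cd$op)))
      stop("duplicate (feature, operator) pair within a rule")
  }
  structure(list(rules = rules, default_class = as.character(default_class)),
            class = "rule_set")
}

new_rule <- function(feature, op, threshold, class) {
  list(conditions = data.frame(feature = as.character(feature),
                               op = as.character(op),
                               threshold = as.numeric(threshold),
                               stringsAsFactors = FALSE),
       class = class)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> ", length(x$rules), " rules + default \"",
      x$default_class, "\"\n", sep = "")
  cat(format_rule_lines(x), sep = "\n")
  invisible(x)
}

format_rule_lines <- function(rs) {
  lines <- vapply(rs$rules, function(r) {
    conds <- paste0(r$conditions$feature, r$conditions$op,
                    format_roundtrip(r$conditions$threshold))
    paste0("IF ", paste(conds, collapse = " AND "),
           " THEN type = \"", r$class, "\"")
  }, character(1))
  c(lines, paste0("IF Others THEN type = \"", rs$default_class, "\""))
}

#' Serialize / parse rule sets
#'
#' One rule per line in the dialect
#' `IF <feature><=x AND <feature>>=y THEN type = "<class>"`, with a final
#' `IF Others THEN type = "<class>"` line for the default class.  Thresholds
#' are printed with the shortest decimal expansion that round-trips, so
#' `read_rules(write_rules(rs))` reproduces `rs` exactly.
#'
#' @param rs A [rule_set()].
#' @param path File path.
#' @return `write_rules` returns `path` invisibly; `read_rules` a [rule_set()].
#' @export
write_rules <- function(rs, path) {
  stopifnot(inherits(rs, "rule_set"))
  writeLines(format_rule_lines(rs), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty rule file: ", path)
  rules <- list()
  default_class <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec(
      "^IF (.+) THEN type = \"(.+)\"$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed rule at line ", i, ": ", ln)
    cls <- m[3L]
    if (m[2L] == "Others") {
      if (!is.null(default_class))
        stop("malformed rule at line ", i, ": second default rule")
      default_class <- cls
      next
    }
    if (!is.null(default_class))
      stop("malformed rule at line ", i, ": rule after the default rule")
    parts <- strsplit(m[2L], " AND ", fixed = TRUE)[[1L]]
    cm <- regmatches(parts, regexec("^(.+?)(<=|>=)([-0-9.eE+]+)$", parts))
    if (any(lengths(cm) != 4L))
      stop("malformed condition at line ", i, ": ",
           parts[which(lengths(cm) != 4L)[1L]])
    thr <- suppressWarnings(as.numeric(vapply(cm, `[`, "", 4L)))
    if (anyNA(thr))
      stop("malformed threshold at line ", i)
    rules[[length(rules) + 1L]] <- list(
      conditions = data.frame(feature = vapply(cm, `[`, "", 2L),
                              op = vapply(cm, `[`, "", 3L),
                              threshold = thr, stringsAsFactors = FALSE),
      class = cls)
  }
  if (is.null(default_class))
    stop("rule file lacks the final 'IF Others' default rule")
  rule_set(rules, default_class)
}

#' Classify samples by first-match rule application
#'
#' Walks the ordered rules; the first rule whose conditions all hold assigns
#' its class, and the default class covers everything else.
#'
#' @param rs A [rule_set()].
#' @param sample Named numeric vector of intensities covering every feature
#'   the rules reference.
#' @return The assigned class label (character scalar).
#' @export
apply_rules <- function(rs, sample) {
  stopifnot(inherits(rs, "rule_set"))
  for (r in rs$rules) {
    cd <- r$conditions
    vals <- sample[cd$feature]
    if (anyNA(vals)) {
      missing <- cd$feature[!cd$feature %in% names(sample)]
      if (length(missing))
        stop("sample lacks feature referenced by a rule: ", missing[1L])
    }
    ok <- ifelse(cd$op == "<=", vals <= cd$threshold, vals >= cd$threshold)
    ok[is.na(ok)] <- FALSE
    if (all(ok)) return(r$class)
  }
  rs$default_class
}

#' @rdname apply_rules
#' @param m An [expression_matrix()]; one label is produced per sample.
#' @export
predict_rules <- function(rs, m) {
  stopifnot(inherits(m, "expression_matrix"))
  vapply(seq_len(nrow(m$values)), function(i) {
    apply_rules(rs, stats::setNames(m$values[i, ], feature_ids(m)))
  }, character(1))
}
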