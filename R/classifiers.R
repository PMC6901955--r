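#' Base-learner specification
#'
#' Uniform train/predict contract for the two classifiers used inside
#' incremental feature selection: a random forest, and a one-vs-rest
#' ensemble of binary support vector machines (libsvm's SMO-family solver,
#' linear kernel by default).
#'
#' @param kind `"rf"` or `"svm"`.
#' @param ntree Number of trees for the random forest (default 100).
#' @param cost Regularization constant C for the SVM (default 1, must be
#'   positive).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param seed Integer seed threaded into training.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("rf", "svm"), ntree = 100, cost = 1,
                            kernel = c("linear", "radial"), seed = 1) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  if (ntree < 1) stop("`ntree` must be >= 1")
  if (cost <= 0) stop("`cost` must be > 0")
  structure(list(kind = kind, ntree = as.integer(ntree), cost = cost,
                 kernel = kernel, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a classifier on a feature subset
#'
#' The model is restricted to the named features (set semantics: the subset
#' is canonicalized by sorting, so feature order does not matter) and is
#' deterministic given the spec's seed.
#'
#' @param spec A [classifier_spec()].
#' @param em A fully imputed [expression_matrix()] with >= 2 classes among
#'   the training labels.
#' @param features Character vector of feature ids to use.
#' @return A trained model of class `imsig_model`.
#' @export
train_classifier <- function(spec, em, features) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(em, "expression_matrix"))
  if (length(features) == 0L) stop("empty feature subset")
  unknown <- setdiff(features, feature_ids(em))
  if (length(unknown)) stop("unknown feature: ", unknown[1L])
  features <- sort(unique(features))
  x <- em$values[, features, drop = FALSE]
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  y <- droplevels(factor(em$labels))
  if (nlevels(y) < 2) stop("single-class training data")

  fit <- if (spec$kind == "rf") {
    set.seed(spec$seed)
    randomForest::randomForest(x = x, y = y, ntree = spec$ntree)
  } else {
    train_ovr_svm(x, y, spec)
  }
  structure(list(spec = spec, features = features, classes = levels(y),
                 fit = fit),
            class = "imsig_model")
}

# One-vs-rest layer: one binary SVM per class; a sample is assigned the
# class with the largest oriented decision value.
train_ovr_svm <- function(x, y, spec) {
  lapply(stats::setNames(levels(y), levels(y)), function(cl) {
    y2 <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    set.seed(spec$seed)
    fit <- e1071::svm(x = x, y = y2, kernel = spec$kernel, cost = spec$cost,
                      scale = FALSE)
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1L]
    # libsvm's decision-value sign depends on label encounter order; orient
    # it so positive means "this class"
    orient <- if (mean(dv[y2 == "pos"]) >= mean(dv[y2 == "rest"])) 1 else -1
    list(fit = fit, orient = orient)
  })
}

#' @export
predict.imsig_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_matrix")) newdata <- newdata$values
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) stop("matrix lacks model feature: ", missing[1L])
  x <- newdata[, object$features, drop = FALSE]
  if (object$spec$kind == "rf") {
    as.character(predict(object$fit, x))
  } else {
    scores <- vapply(object$fit, function(b) {
      dv <- attr(predict(b$fit, x, decision.values = TRUE),
                 "decision.values")[, 1L]
      b$orient * dv
    }, numeric(nrow(x)))
    if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1,
                                        dimnames = list(NULL, names(object$fit)))
    # ties -> lexicographically first class
    object$classes[apply(scores, 1L, which.max)]
  }
}

#' @export
print.imsig_model <- function(x, ...) {
  cat("<imsig_model> ", toupper(x$spec$kind), ", ", length(x$features),
      " features, classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
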