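#' Seeded stratified fold assignment
#'
#' @param labels Class label per sample.
#' @param k Number of folds (>= 2, at most the smallest class size).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per sample; every class
#'   is spread across the folds as evenly as possible.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  if (k < 2) stop("`k` must be >= 2")
  smallest <- min(table(labels))
  if (k > smallest)
    stop("folds = ", k, " exceeds the smallest class size (", smallest,
         "); use fewer folds")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated evaluation of one feature subset
#'
#' Stratified k-fold cross-validation with seeded fold assignment; the
#' out-of-fold predictions are pooled and scored once (confusion matrix,
#' per-class and overall accuracy, multi-class MCC).
#'
#' @param em A fully imputed [expression_matrix()].
#' @param features Feature ids to use (non-empty).
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return An `evaluation_report` (see [evaluate_predictions()]), with the
#'   pooled out-of-fold predictions attached as attribute `predictions`.
#' @export
evaluate_subset <- function(em, features, spec, folds = 10, seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(features) == 0L) stop("empty feature subset")
  fold_of <- stratified_folds(em$labels, folds, seed)
  truth <- as.character(em$labels)
  pred <- character(length(truth))
  for (f in seq_len(folds)) {
    train <- subset_matrix(em, samples = which(fold_of != f))
    model <- train_classifier(spec, train, features)
    pred[fold_of == f] <-
      predict(model, em$values[fold_of == f, , drop = FALSE])
  }
  rep <- evaluate_predictions(truth, pred)
  attr(rep, "predictions") <- stats::setNames(pred, sample_ids(em))
  rep
}

#' Incremental feature selection configuration
#'
#' @param step Coarse scan step over prefix sizes (default 10).
#' @param window Refinement half-window around the coarse optimum (default
#'   10, scanned with step 1).
#' @param cap Largest prefix size scanned in the coarse stage; `NULL` scans
#'   the whole ranked list.
#' @param folds Cross-validation folds (default 10).
#' @param spec A [classifier_spec()].
#' @param seed Seed for the fold assignment (shared by both stages, so the
#'   coarse optimum re-evaluates identically during refinement).
#' @return An `ifs_config` list.
#' @export
ifs_config <- function(step = 10, window = 10, cap = NULL, folds = 10,
                       spec = classifier_spec("rf"), seed = 1) {
  if (step < 1) stop("`step` must be >= 1")
  if (window < 1) stop("`window` must be >= 1")
  if (folds < 2) stop("`folds` must be >= 2")
  stopifnot(inherits(spec, "classifier_spec"))
  structure(list(step = as.integer(step), window = as.integer(window),
                 cap = if (is.null(cap)) NULL else as.integer(cap),
                 folds = as.integer(folds), spec = spec,
                 seed = as.integer(seed)),
            class = "ifs_config")
}

#' Two-stage incremental feature selection
#'
#' Stage 1 evaluates prefixes of the ranked list of sizes `step, 2*step, ...`
#' up to the cap by cross-validated MCC; around the coarse optimum s* it then
#' evaluates every size in `[max(1, s* - window), s* + window]` (clipped to
#' the list length).  The reported optimum is the argmax over all evaluated
#' sizes, ties resolved toward the smaller subset.
#'
#' @param em A fully imputed [expression_matrix()].
#' @param ranked Ranking from [run_mcfs()] (or any data frame with a
#'   `feature_id` column covering the matrix features).
#' @param cfg An [ifs_config()].
#' @return An `ifs_result`: list with `curve` (data frame of size, mcc,
#'   accuracy, stage), `reports` (per-size evaluation reports, named by
#'   size), `optimal_size`, `optimal_features` (that prefix of the ranking)
#'   and `optimal_report`.
#' @export
run_ifs <- function(em, ranked, cfg = ifs_config()) {
  stopifnot(inherits(em, "expression_matrix"), inherits(cfg, "ifs_config"))
  feats <- ranked$feature_id
  if (length(feats) == 0L) stop("empty ranked feature list")
  unknown <- setdiff(feats, feature_ids(em))
  if (length(unknown)) stop("ranked feature absent from matrix: ", unknown[1L])

  cap <- min(if (is.null(cfg$cap)) length(feats) else cfg$cap, length(feats))
  sizes1 <- seq(cfg$step, cap, by = cfg$step)
  if (length(sizes1) == 0L) sizes1 <- cap

  reports <- new.env(parent = emptyenv())
  eval_size <- function(s) {
    key <- as.character(s)
    if (is.null(reports[[key]]))
      reports[[key]] <- evaluate_subset(em, feats[seq_len(s)], cfg$spec,
                                        cfg$folds, cfg$seed)
    reports[[key]]
  }

  for (s in sizes1) eval_size(s)
  mcc1 <- vapply(sizes1, function(s) eval_size(s)$mcc, numeric(1))
  s_star <- sizes1[which.max(mcc1)]   # ties -> smaller size (first max)

  sizes2 <- seq(max(1L, s_star - cfg$window),
                min(length(feats), s_star + cfg$window))
  for (s in sizes2) eval_size(s)

  all_sizes <- sort(unique(c(sizes1, sizes2)))
  curve <- data.frame(
    size = all_sizes,
    mcc = vapply(all_sizes, function(s) eval_size(s)$mcc, numeric(1)),
    accuracy = vapply(all_sizes, function(s) eval_size(s)$accuracy,
                      numeric(1)),
    stage = ifelse(all_sizes %in% sizes1,
                   ifelse(all_sizes %in% sizes2, "both", "coarse"),
                   "refine"))
  opt <- all_sizes[which.max(curve$mcc)]  # sorted sizes: first max = smallest
  structure(list(curve = curve,
                 reports = stats::setNames(
                   lapply(all_sizes, eval_size), all_sizes),
                 optimal_size = opt,
                 optimal_features = feats[seq_len(opt)],
                 optimal_report = eval_size(opt)),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("<ifs_result> optimal size %d, MCC %.4f (%d sizes evaluated)\n",
              x$optimal_size, x$optimal_report$mcc, nrow(x$curve)))
  invisible(x)
}
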