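#' Monte Carlo feature selection configuration
#'
#' @param m Features per random subset (`m << M`); default `ceiling(sqrt(M))`,
#'   resolved against the matrix at run time when `NULL`.
#' @param t Number of random feature subsets (default 1000).
#' @param p Decision trees per subset, each grown on a bootstrap resample of
#'   the samples (default 5), giving `p * t` trees in total.
#' @param u Exponent on the per-tree balanced accuracy weight (default 1).
#' @param v Exponent on the node sample fraction (default 1).
#' @param min_leaf Minimum samples per leaf of the trees (default 2).
#' @param seed Integer seed; the run is reproducible from it.
#' @return An `mcfs_config` list.
#' @export
mcfs_config <- function(m = NULL, t = 1000, p = 5, u = 1, v = 1,
                        min_leaf = 2, seed = 1) {
  if (!is.null(m) && m < 1) stop("`m` must be >= 1")
  if (t < 1) stop("`t` must be >= 1")
  if (p < 1) stop("`p` must be >= 1")
  if (min_leaf < 1) stop("`min_leaf` must be >= 1")
  structure(list(m = if (is.null(m)) NULL else as.integer(m),
                 t = as.integer(t), p = as.integer(p), u = u, v = v,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "mcfs_config")
}

#' Rank features by Monte Carlo relative importance
#'
#' Draws `t` feature subsets of size `m` uniformly without replacement, grows
#' `p` entropy decision trees per subset on bootstrap resamples of the
#' samples, scores each tree by balanced accuracy (mean per-class recall) on
#' its out-of-bag samples, and accumulates for every feature g the relative
#' importance
#' \deqn{RI_g = \sum_{\tau=1}^{p t} (wAcc_\tau)^u \sum_{n_g(\tau)}
#'   IG(n_g(\tau)) \left(\frac{no.in\; n_g(\tau)}{no.in\; \tau}\right)^v,}
#' the sum over all nodes split on g of base-2 information gain times the
#' node's training-sample fraction.  A feature never drawn or never used as
#' a split scores 0.
#'
#' Samples are processed in sorted sample-identifier order, so the ranking
#' is invariant to row permutations of the input.
#'
#' @param em A fully imputed [expression_matrix()] with at least two classes
#'   and at least two samples per class.
#' @param cfg An [mcfs_config()].
#' @param collect_trees If `TRUE`, attach per-tree records (feature
#'   contributions and out-of-bag balanced accuracy) as attribute `trees`.
#' @return A data frame (`feature_id`, `ri`) sorted by decreasing RI, ties
#'   broken by feature identifier.
#' @export
run_mcfs <- function(em, cfg = mcfs_config(), collect_trees = FALSE) {
  stopifnot(inherits(em, "expression_matrix"), inherits(cfg, "mcfs_config"))
  if (anyNA(em$values))
    stop("matrix contains missing values; impute first")
  M <- ncol(em$values)
  m <- if (is.null(cfg$m)) as.integer(ceiling(sqrt(M))) else cfg$m
  if (m > M) stop("`m` = ", m, " exceeds the ", M, " available features")
  y <- factor(em$labels)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  small <- table(y) < 2
  if (any(small))
    stop("class with < 2 samples: ", names(which(small))[1L])

  ord <- order(sample_ids(em))
  X <- em$values[ord, , drop = FALSE]
  yc <- as.integer(y[ord]) - 1L

  set.seed(cfg$seed)
  res <- mcfs_run_cpp(X, yc, nlevels(y), m, cfg$t, cfg$p, cfg$u, cfg$v,
                      cfg$min_leaf, collect_trees)
  ri <- res$ri
  ids <- feature_ids(em)
  o <- order(-ri, ids)
  out <- data.frame(feature_id = ids[o], ri = ri[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", "data.frame")
  if (collect_trees) {
    trees <- lapply(res$trees, function(tr) {
      tr$features <- ids[tr$features]
      tr
    })
    attr(out, "trees") <- trees
  }
  out
}

#' Grow a single entropy decision tree
#'
#' The tree learner used inside [run_mcfs()], exposed for inspection: a
#' top-down binary tree with base-2 entropy impurity, grown to purity under
#' a minimum-leaf constraint, no pruning.  The returned object records, per
#' internal node, the split feature, its information gain in bits and its
#' training-sample count, from which relative-importance contributions can
#' be verified by hand.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Class labels, length `nrow(x)`.
#' @param min_leaf Minimum samples per leaf (default 2).
#' @param v Exponent on the node sample fraction used when accumulating
#'   per-feature contributions (default 1).
#' @return An `imsig_tree` with elements `nodes` (data frame of per-node
#'   feature, threshold, information gain, sample count), `contrib` (named
#'   per-feature sum of `IG * (n_node/n_root)^v`) and the flat tree arrays.
#' @export
decision_tree <- function(x, y, min_leaf = 2, v = 1) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  y <- factor(y)
  tr <- grow_tree_cpp(x, as.integer(y) - 1L, nlevels(y), min_leaf, v)
  internal <- tr$feature >= 0
  nodes <- data.frame(feature = colnames(x)[tr$feature[internal] + 1L],
                      threshold = tr$threshold[internal],
                      ig = tr$ig[internal],
                      n_node = tr$n_node[internal],
                      stringsAsFactors = FALSE)
  structure(list(tree = tr, nodes = nodes, n_root = tr$n_root,
                 contrib = stats::setNames(tr$contrib, colnames(x)),
                 classes = levels(y), features = colnames(x)),
            class = "imsig_tree")
}

#' @export
predict.imsig_tree <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$features, drop = FALSE]
  object$classes[predict_tree_cpp(object$tree, newdata) + 1L]
}

#' Relative-importance contribution of one tree
#'
#' Multiplies a tree's per-feature `IG * (n_node/n_root)^v` sums by its
#' accuracy weight `wAcc^u`: the exact per-tree term of the RI equation.
#'
#' @param tree An `imsig_tree` from [decision_tree()].
#' @param wacc The tree's balanced accuracy on its evaluation samples.
#' @param u Exponent on `wacc` (default 1).
#' @return Named numeric vector of per-feature RI contributions.
#' @export
tree_ri_contribution <- function(tree, wacc, u = 1) {
  stopifnot(inherits(tree, "imsig_tree"), wacc >= 0, wacc <= 1)
  wacc^u * tree$contrib
}

#' Select informative features by label-permutation testing
#'
#' Runs MCFS once on the observed labels and `n_perm` more times on
#' label-permuted copies (features fixed, labels shuffled, seeds
#' `seed + 1 ... seed + n_perm`).  For each feature a one-sided one-sample
#' t-test asks whether the observed RI exceeds the mean of its permuted RI
#' values; p-values are Benjamini-Hochberg adjusted, and the informative set
#' is the head of the RI ranking sized by the number of features significant
#' at `alpha` — a prefix, matching how the informative features head the
#' reported ranking.
#'
#' @inheritParams run_mcfs
#' @param n_perm Number of label permutations (>= 2; the t-test needs
#'   replicates).
#' @param alpha Significance level after adjustment (default 0.05).
#' @return Character vector of informative feature ids (RI order), with the
#'   full test table attached as attribute `table` and the observed ranking
#'   as attribute `ranking`.
#' @export
informative_cutoff <- function(em, cfg = mcfs_config(), n_perm = 20,
                               alpha = 0.05) {
  if (n_perm < 2) stop("`n_perm` must be >= 2 (the t-test needs replicates)")
  ranked <- run_mcfs(em, cfg)
  obs <- stats::setNames(ranked$ri, ranked$feature_id)

  perm <- matrix(NA_real_, nrow(ranked), n_perm,
                 dimnames = list(ranked$feature_id, NULL))
  for (i in seq_len(n_perm)) {
    set.seed(cfg$seed + i)
    perm_labels <- sample(as.character(em$labels))
    em_i <- expression_matrix(em$values, perm_labels)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    r_i <- run_mcfs(em_i, cfg_i)
    perm[r_i$feature_id, i] <- r_i$ri
  }

  mu <- rowMeans(perm)
  s <- apply(perm, 1L, sd)
  # One-sided t-test of the observed RI against its permutation null.  The
  # observed value is a single draw, so the comparison uses the prediction
  # scaling s * sqrt(1 + 1/n): under exchangeability the statistic is
  # t-distributed with n_perm - 1 df and the p-values are calibrated.
  tstat <- (mu - obs) / (s * sqrt(1 + 1 / n_perm))
  pval <- pt(tstat, df = n_perm - 1)
  pval[s == 0] <- ifelse(obs[s == 0] > mu[s == 0], 0, 1)
  padj <- p.adjust(pval, method = "BH")
  # the informative set is reported as the head of the RI ranking, sized by
  # the number of significant features (the ranking's "first N features")
  keep <- head(ranked$feature_id, sum(padj < alpha))

  tab <- data.frame(feature_id = ranked$feature_id, ri = ranked$ri,
                    perm_mean = mu, perm_sd = s, p = pval, p_adj = padj,
                    stringsAsFactors = FALSE)
  structure(keep, table = tab, ranking = ranked)
}

#' Write a ranked feature list as two-column TSV
#'
#' @param ranked Data frame from [run_mcfs()].
#' @param path Output path.
#' @export
write_ranked_features <- function(ranked, path) {
  write.table(data.frame(feature_id = ranked$feature_id,
                         ri = format_roundtrip(ranked$ri)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
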