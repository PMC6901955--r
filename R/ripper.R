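# RIPPER ordered rule induction (Repeated Incremental Pruning to Produce
# Error Reduction).  Classes are processed in order of increasing
# prevalence; per class, conjunctive threshold rules are grown
# condition-by-condition by FOIL information gain on 2/3 of the data,
# pruned on the held-out 1/3 by (p - n)/(p + n), accepted under a
# description-length budget (stop when total DL exceeds the minimum seen by
# more than 64 bits), then revised by two optimization passes choosing
# between the original rule, a regrown replacement and a greedy revision by
# total DL.  The most prevalent class becomes the default.

covers_conds <- function(conds, X) {
  ok <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(conds))) {
    v <- X[, conds$feature[i]]
    ok <- ok & if (conds$op[i] == "<=") v <= conds$threshold[i]
               else v >= conds$threshold[i]
  }
  ok
}

covers_any <- function(rule_list, X) {
  out <- rep(FALSE, nrow(X))
  for (conds in rule_list) out <- out | covers_conds(conds, X)
  out
}

# FOIL-gain growth of one rule; `conds` may carry a starting rule (revision)
grow_rule <- function(X, ypos, conds = NULL, max_conds = 15L) {
  if (is.null(conds))
    conds <- data.frame(feature = character(0), op = character(0),
                        threshold = numeric(0), stringsAsFactors = FALSE)
  cov <- if (nrow(conds)) covers_conds(conds, X) else rep(TRUE, nrow(X))
  feats <- sort(colnames(X))
  repeat {
    p0 <- sum(ypos & cov); n0 <- sum(!ypos & cov)
    if (p0 == 0L || n0 == 0L || nrow(conds) >= max_conds) break
    base <- log2(p0 / (p0 + n0))
    best <- NULL; best_gain <- 1e-9
    for (f in feats) {
      xv <- X[cov, f]; yv <- ypos[cov]
      o <- order(xv)
      xs <- xv[o]; ys <- yv[o]
      b <- which(diff(xs) > 0)
      if (!length(b)) next
      thr <- (xs[b] + xs[b + 1L]) / 2
      cp <- cumsum(ys); cn <- cumsum(!ys)
      for (side in c("<=", ">=")) {
        p1 <- if (side == "<=") cp[b] else p0 - cp[b]
        n1 <- if (side == "<=") cn[b] else n0 - cn[b]
        gain <- ifelse(p1 > 0,
                       p1 * (log2(p1 / (p1 + n1)) - base), -Inf)
        j <- order(-gain, thr)[1L]
        if (gain[j] > best_gain) {
          best_gain <- gain[j]
          best <- list(feature = f, op = side, threshold = thr[j])
        }
      }
    }
    if (is.null(best)) break
    same <- conds$feature == best$feature & conds$op == best$op
    if (any(same)) {      # tighten instead of duplicating (feature, op)
      conds$threshold[same] <- if (best$op == "<=")
        min(conds$threshold[same], best$threshold)
      else max(conds$threshold[same], best$threshold)
    } else {
      conds <- rbind(conds, data.frame(feature = best$feature, op = best$op,
                                       threshold = best$threshold,
                                       stringsAsFactors = FALSE))
    }
    cov <- cov & (if (best$op == "<=") X[, best$feature] <= best$threshold
                  else X[, best$feature] >= best$threshold)
  }
  conds
}

# keep the condition prefix maximizing (p - n)/(p + n) on the prune split
prune_rule <- function(conds, Xp, yp) {
  k <- nrow(conds)
  if (k <= 1L || nrow(Xp) == 0L) return(conds)
  val <- numeric(k)
  for (i in seq_len(k)) {
    cov <- covers_conds(conds[seq_len(i), , drop = FALSE], Xp)
    p <- sum(yp & cov); n <- sum(!yp & cov)
    val[i] <- if (p + n == 0L) 0 else (p - n) / (p + n)
  }
  keep <- which(val >= max(val) - 1e-12)[1L]   # ties -> shortest rule
  conds[seq_len(keep), , drop = FALSE]
}

ruleset_dl <- function(rule_list, X, ypos, t_count) {
  n <- nrow(X)
  theory <- sum(vapply(rule_list, function(cd) {
    k <- nrow(cd)
    0.5 * (log2(k + 1) + k * log2(max(t_count, 2)))
  }, numeric(1)))
  covered <- covers_any(rule_list, X)
  cov <- sum(covered); unc <- n - cov
  fp <- sum(covered & !ypos); fn <- sum(!covered & ypos)
  data_dl <- lchoose(cov, fp) / log(2) + lchoose(unc, fn) / log(2) +
    log2(cov + 1) + log2(unc + 1)
  theory + data_dl
}

grow_prune_split <- function(idx_pos, idx_neg) {
  sp <- function(idx) {
    idx <- if (length(idx) > 1L) sample(idx) else idx
    ng <- ceiling(2 / 3 * length(idx))
    list(grow = idx[seq_len(ng)],
         prune = if (ng < length(idx)) idx[(ng + 1L):length(idx)] else integer(0))
  }
  a <- sp(idx_pos); b <- sp(idx_neg)
  list(grow = c(a$grow, b$grow), prune = c(a$prune, b$prune))
}

grow_and_prune <- function(X, ypos, active, start = NULL) {
  s <- grow_prune_split(which(active & ypos), which(active & !ypos))
  conds <- grow_rule(X[s$grow, , drop = FALSE], ypos[s$grow], conds = start)
  if (nrow(conds) == 0L) return(NULL)
  prune_rule(conds, X[s$prune, , drop = FALSE], ypos[s$prune])
}

learn_class_rules <- function(X, ypos, dl_slack = 64) {
  n <- nrow(X)
  t_count <- sum(vapply(colnames(X),
                        function(f) 2L * max(length(unique(X[, f])) - 1L, 0L),
                        integer(1)))
  rules <- list()
  covered <- rep(FALSE, n)
  dl_min <- ruleset_dl(rules, X, ypos, t_count)

  add_rules <- function() {
    repeat {
      active <- !covered
      if (!any(ypos & active)) break
      conds <- grow_and_prune(X, ypos, active)
      if (is.null(conds)) break
      cov <- covers_conds(conds, X)
      if (!any(cov & active & ypos)) break
      cand <- c(rules, list(conds))
      dl <- ruleset_dl(cand, X, ypos, t_count)
      if (dl > dl_min + dl_slack) break
      dl_min <<- min(dl_min, dl)
      rules <<- cand
      covered <<- covered | cov
    }
  }
  add_rules()

  for (pass in 1:2) {
    for (i in seq_along(rules)) {
      others <- rules[-i]
      sub <- !covers_any(others, X)
      if (!any(ypos & sub)) next
      variants <- list(original = rules[[i]])
      repl <- grow_and_prune(X, ypos, sub)
      if (!is.null(repl)) variants$replacement <- repl
      rev <- grow_and_prune(X, ypos, sub, start = rules[[i]])
      if (!is.null(rev)) variants$revision <- rev
      dls <- vapply(variants, function(v) {
        ruleset_dl(c(others, list(v)), X, ypos, t_count)
      }, numeric(1))
      rules[[i]] <- variants[[which.min(dls)]]
    }
    covered <- covers_any(rules, X)
    dl_min <- min(dl_min, ruleset_dl(rules, X, ypos, t_count))
  }
  add_rules()   # mop up positives uncovered after optimization

  # ordered-list semantics: drop rules covering no new positive
  kept <- list()
  seen <- rep(FALSE, n)
  for (conds in rules) {
    cov <- covers_conds(conds, X)
    if (any(cov & !seen & ypos)) {
      kept <- c(kept, list(conds))
      seen <- seen | cov
    }
  }
  kept
}

#' Induce an ordered rule set with RIPPER
#'
#' Learns interpretable IF-THEN intensity rules over the given features.
#' Classes are handled from rarest to most prevalent (prevalence ties break
#' lexicographically); the most prevalent class supplies the default rule.
#' Samples covered by an earlier class's rules are removed before the next
#' class is learned, matching first-match application.
#'
#' @param em A fully imputed [expression_matrix()].
#' @param features Feature ids available to the rules (non-empty).
#' @param seed Integer seed for the internal grow/prune splits.
#' @return A [rule_set()].  Single-class input yields zero rules with that
#'   class as default.
#' @export
ripper_train <- function(em, features, seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(features) == 0L) stop("empty feature set")
  unknown <- setdiff(features, feature_ids(em))
  if (length(unknown)) stop("unknown feature: ", unknown[1L])
  X <- em$values[, features, drop = FALSE]
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  y <- as.character(em$labels)
  tab <- table(y)
  ord <- names(tab)[order(tab, names(tab))]   # increasing prevalence
  default_class <- ord[length(ord)]
  if (length(ord) == 1L) return(rule_set(list(), default_class))

  set.seed(seed)
  rules <- list()
  active <- rep(TRUE, nrow(X))
  for (cl in ord[-length(ord)]) {
    idx <- which(active)
    if (!any(y[idx] == cl)) next
    class_rules <- learn_class_rules(X[idx, , drop = FALSE], y[idx] == cl)
    for (conds in class_rules)
      rules <- c(rules, list(list(conditions = conds, class = cl)))
    if (length(class_rules))
      active[idx] <- active[idx] & !covers_any(class_rules,
                                               X[idx, , drop = FALSE])
  }
  rule_set(rules, default_class)
}

#' Cross-validated evaluation of the rule-learning arm
#'
#' For each repeat, draws a fresh stratified fold split; per fold, applies
#' the Johnson reducer and RIPPER on the training folds and classifies the
#' held-out fold by first-match rule application.  Out-of-fold predictions
#' are pooled and scored per repeat; the reported MCC and accuracies are
#' means over repeats and the confusion matrices are summed.
#'
#' @param em A fully imputed [expression_matrix()].
#' @param features Informative feature ids fed to the reducer.
#' @param repeats Number of repeated cross-validations (default 3).
#' @param folds Folds per repeat (default 10).
#' @param seed Integer seed.
#' @return List with `mcc`, `accuracy`, `per_class_accuracy` (means over
#'   repeats), `confusion` (summed) and `reports` (per-repeat
#'   `evaluation_report`s).
#' @export
evaluate_rules <- function(em, features, repeats = 3, folds = 10, seed = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (repeats < 1) stop("`repeats` must be >= 1")
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rep_seed <- seed + (r - 1L) * 1000L
    fold_of <- stratified_folds(em$labels, folds, rep_seed)
    truth <- as.character(em$labels)
    pred <- character(length(truth))
    for (f in seq_len(folds)) {
      train <- subset_matrix(em, samples = which(fold_of != f))
      reduct <- johnson_reduce(train, features)
      if (length(reduct) == 0L) reduct <- features
      rs <- ripper_train(train, reduct, seed = rep_seed + f)
      test <- subset_matrix(em, samples = which(fold_of == f))
      pred[fold_of == f] <- predict_rules(rs, test)
    }
    reports[[r]] <- evaluate_predictions(truth, pred)
  }
  confusion <- Reduce(`+`, lapply(reports, function(x) unclass(x$confusion)))
  list(mcc = mean(vapply(reports, `[[`, numeric(1), "mcc")),
       accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy")),
       per_class_accuracy = rowMeans(vapply(
         reports, `[[`, numeric(nrow(confusion)), "per_class_accuracy")),
       confusion = confusion,
       reports = reports)
}
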