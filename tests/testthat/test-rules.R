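# Johnson reducer, MDL discretization and RIPPER induction.

test_that("MDL discretization cuts a clean two-class feature once, between groups", {
  set.seed(3)
  x <- c(rnorm(30, 0, 0.3), rnorm(30, 4, 0.3))
  y <- rep(c("A", "B"), each = 30)
  cuts <- mdl_discretize(x, y)
  expect_length(cuts, 1L)
  expect_gt(cuts, max(x[y == "A"]) - 1e-9)
  expect_lt(cuts, min(x[y == "B"]) + 1e-9)
  # pure-noise feature: no accepted cut
  expect_length(mdl_discretize(rnorm(60), y), 0L)
})

test_that("a single discerning feature yields a singleton reduct", {
  D <- cbind(f1 = c(1, 1, 2, 2), f2 = c(1, 2, 1, 2), f3 = c(1, 1, 1, 2))
  expect_identical(johnson_reduce_discrete(D, c("A", "A", "B", "B")), "f1")
})

test_that("a single-class table has nothing to discern", {
  D <- cbind(f1 = c(1, 2, 3), f2 = c(1, 1, 2))
  expect_identical(johnson_reduce_discrete(D, rep("A", 3)), character(0))
  expect_error(johnson_reduce_discrete(D[, 0], rep("A", 3)), "empty feature")
})

test_that("the greedy reduct covers all discernible pairs near-minimally", {
  set.seed(17)
  for (i in 1:8) {
    D <- matrix(sample(0:2, 30 * 8, replace = TRUE), 30, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    labels <- sample(c("A", "B", "C"), 30, replace = TRUE)
    red <- johnson_reduce_discrete(D, labels)
    # coverage: the reduct discerns every pair the full table discerns
    pairs <- which(outer(labels, labels, "!=") & upper.tri(diag(30)),
                   arr.ind = TRUE)
    neq_all <- D[pairs[, 1], ] != D[pairs[, 2], ]
    target <- rowSums(neq_all) > 0
    neq_red <- neq_all[, red, drop = FALSE]
    expect_true(all(rowSums(neq_red[target, , drop = FALSE]) > 0))
    expect_lte(length(red), min_cover_size(D, labels) + 1L)
  }
})

test_that("RIPPER finds the separating threshold inside the class gap", {
  set.seed(5)
  lo <- runif(25, 0.2, 0.7)
  hi <- runif(25, 0.9, 1.5)
  em <- expression_matrix(
    matrix(c(lo, hi), ncol = 1,
           dimnames = list(sprintf("S%02d", 1:50), "pep1")),
    rep(c("A", "B"), each = 25))
  rs <- ripper_train(em, "pep1", seed = 2)
  expect_length(rs$rules, 1L)
  cond <- rs$rules[[1]]$conditions
  thr <- cond$threshold[1]
  expect_gt(thr, max(lo))
  expect_lt(thr, min(hi))
  expect_equal(multiclass_mcc(as.character(em$labels), predict_rules(rs, em)),
               1.0)
  # exhaustive midpoint oracle: perfect separators exist exactly inside the
  # class gap, and the learned threshold separates as well as the best one
  x <- sort(em$values[, 1])
  mids <- (x[-1] + x[-length(x)]) / 2
  perfect <- mids[vapply(mids, function(t0) {
    all((em$values[, 1] <= t0) == (em$labels == "A"))
  }, logical(1))]
  expect_gt(length(perfect), 0L)
  expect_true(all(perfect > max(lo) & perfect < min(hi)))
  expect_true(all((em$values[, 1] <= thr) == (em$labels == "A")))
})

test_that("single-class input yields an empty rule list with that default", {
  em <- expression_matrix(matrix(1:6 + 0.0, 3, 2,
                                 dimnames = list(paste0("S", 1:3),
                                                 paste0("P", 1:2))),
                          rep("only", 3))
  rs <- ripper_train(em, paste0("P", 1:2), seed = 1)
  expect_length(rs$rules, 0L)
  expect_equal(rs$default_class, "only")
  expect_equal(apply_rules(rs, c(P1 = 1, P2 = 2)), "only")
  expect_error(ripper_train(em, character(0)), "empty feature")
})

test_that("RIPPER recovers planted one-feature class rules", {
  dat <- make_planted_rule_data(seed = 23)
  em <- dat$matrix
  rs <- ripper_train(em, feature_ids(em), seed = 3)
  expect_equal(rs$default_class, "Background")
  for (cl in names(dat$planted)) {
    used <- unlist(lapply(rs$rules[vapply(rs$rules, `[[`, "", "class") == cl],
                          function(r) r$conditions$feature))
    expect_true(dat$planted[[cl]] %in% used)
  }
  mcc <- multiclass_mcc(as.character(em$labels), predict_rules(rs, em))
  expect_gte(mcc, 0.95)
  # learned thresholds sit strictly between observed training values
  for (r in rs$rules) {
    for (i in seq_len(nrow(r$conditions))) {
      v <- em$values[, r$conditions$feature[i]]
      thr <- r$conditions$threshold[i]
      expect_true(any(v < thr) && any(v > thr))
      expect_false(any(v == thr))
    }
  }
  # every rule covers at least one training sample of its class
  for (r in rs$rules) {
    cov <- vapply(seq_len(nrow(em$values)), function(s) {
      cd <- r$conditions
      all(ifelse(cd$op == "<=", em$values[s, cd$feature] <= cd$threshold,
                 em$values[s, cd$feature] >= cd$threshold))
    }, logical(1))
    expect_gt(sum(cov & as.character(em$labels) == r$class), 0L)
  }
})

test_that("the reduct preserves rule-training accuracy within 5 points", {
  dat <- make_planted_rule_data(seed = 29, n_extra = 4)
  em <- dat$matrix
  reduct <- johnson_reduce(em, feature_ids(em))
  expect_true(all(reduct %in% feature_ids(em)))
  acc_of <- function(feats) {
    rs <- ripper_train(em, feats, seed = 7)
    mean(predict_rules(rs, em) == as.character(em$labels))
  }
  expect_lt(abs(acc_of(feature_ids(em)) - acc_of(reduct)), 0.05)
})

test_that("repeated rule cross-validation pools, averages and sums correctly", {
  dat <- make_planted_rule_data(seed = 31, per_class = 12, n_background = 16)
  em <- dat$matrix
  ev <- evaluate_rules(em, feature_ids(em), repeats = 2, folds = 4, seed = 5)
  expect_length(ev$reports, 2L)
  expect_equal(ev$mcc, mean(c(ev$reports[[1]]$mcc, ev$reports[[2]]$mcc)))
  expect_equal(sum(ev$confusion), 2L * nrow(em$values))
  expect_gte(ev$mcc, 0.8)               # near-separable planted rules
  one <- evaluate_rules(em, feature_ids(em), repeats = 1, folds = 4, seed = 5)
  expect_length(one$reports, 1L)
  expect_equal(one$mcc, one$reports[[1]]$mcc)
})
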