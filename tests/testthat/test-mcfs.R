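toy_planted <- function(seed = 7) {
  generate_synthetic(synth_config(3, 15, 100, 3, effect_size = 1.5,
                                  noise_sd = 0.5, seed = seed))
}

test_that("a perfect single-stump tree contributes exactly wAcc * IG * fraction", {
  x <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), ncol = 1,
              dimnames = list(NULL, "pep"))
  y <- rep(c("A", "B"), each = 4)
  tr <- decision_tree(x, y)
  expect_equal(nrow(tr$nodes), 1L)          # one root split
  expect_equal(tr$nodes$ig, 1.0)            # 1 bit for a balanced clean split
  expect_equal(tr$nodes$n_node, 8L)
  expect_equal(unname(tree_ri_contribution(tr, wacc = 1)["pep"]), 1.0)
  expect_equal(unname(tree_ri_contribution(tr, wacc = 0.5, u = 2)["pep"]), 0.25)
  expect_identical(predict(tr, x), y)
})

test_that("RI decomposes additively over the per-tree records", {
  g <- toy_planted()
  ranked <- run_mcfs(g$matrix, mcfs_config(t = 30, p = 3, seed = 5),
                     collect_trees = TRUE)
  trees <- attr(ranked, "trees")
  expect_length(trees, 90L)
  acc <- stats::setNames(numeric(ncol(g$matrix$values)),
                         feature_ids(g$matrix))
  for (tr in trees) acc[tr$features] <- acc[tr$features] + tr$contrib
  expect_equal(acc[ranked$feature_id], stats::setNames(ranked$ri,
                                                       ranked$feature_id),
               tolerance = 1e-9)
  expect_true(all(vapply(trees, function(tr) tr$wacc >= 0 && tr$wacc <= 1,
                         logical(1))))
})

test_that("a constant feature is never split on and scores RI zero", {
  g <- toy_planted()
  g$matrix$values[, "P00001"] <- 1.0
  ranked <- run_mcfs(g$matrix, mcfs_config(t = 50, p = 3, seed = 2))
  expect_equal(ranked$ri[ranked$feature_id == "P00001"], 0)
  expect_true(all(ranked$ri >= 0))
  expect_true(all(diff(ranked$ri) <= 0))    # non-increasing scores
  expect_setequal(ranked$feature_id, feature_ids(g$matrix))
})

test_that("the ranking is reproducible and invariant to scaling and row order", {
  g <- toy_planted()
  cfg <- mcfs_config(t = 40, p = 3, seed = 9)
  r1 <- run_mcfs(g$matrix, cfg)
  expect_identical(r1, run_mcfs(g$matrix, cfg))

  scaled <- expression_matrix(g$matrix$values * 7,
                              as.character(g$matrix$labels))
  r_scaled <- run_mcfs(scaled, cfg)
  expect_identical(r_scaled$feature_id, r1$feature_id)
  expect_equal(r_scaled$ri, r1$ri, tolerance = 1e-12)

  perm <- sample(nrow(g$matrix$values))
  shuffled <- expression_matrix(g$matrix$values[perm, ],
                                as.character(g$matrix$labels)[perm])
  expect_identical(run_mcfs(shuffled, cfg), r1)
})

test_that("planted features dominate the ranking", {
  g <- toy_planted()
  ranked <- run_mcfs(g$matrix, mcfs_config(t = 200, p = 5, seed = 4))
  ranks <- match(unlist(g$truth$informative), ranked$feature_id)
  expect_lte(stats::median(ranks), 0.05 * nrow(ranked))
})

test_that("invalid MCFS inputs are rejected", {
  g <- toy_planted()
  expect_error(run_mcfs(g$matrix, mcfs_config(m = 101, t = 5)), "`m`")
  one <- subset_matrix(g$matrix, samples = 1:16)   # one class has 1 sample
  expect_error(run_mcfs(one, mcfs_config(t = 5)), "< 2 samples")
  g$matrix$values[1, 1] <- NA
  expect_error(run_mcfs(g$matrix, mcfs_config(t = 5)), "impute")
})

test_that("the permutation cutoff recovers planted features and needs replicates", {
  g <- toy_planted(seed = 21)
  cfg <- mcfs_config(t = 100, p = 5, seed = 13)
  expect_error(informative_cutoff(g$matrix, cfg, n_perm = 1), "n_perm")
  inf <- informative_cutoff(g$matrix, cfg, n_perm = 8, alpha = 0.05)
  planted <- unlist(g$truth$informative)
  expect_gte(mean(planted %in% inf), 0.8)
  tab <- attr(inf, "table")
  expect_equal(nrow(tab), 100L)
  # prefix of the ranking, sized by the significant-feature count
  expect_identical(as.character(inf), head(tab$feature_id, length(inf)))
  expect_equal(length(inf), sum(tab$p_adj < 0.05))
})
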