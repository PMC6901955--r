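ranked_from_truth <- function(g) {
  # ground-truth-ordered ranking: planted features first, then noise
  planted <- unlist(g$truth$informative)
  ids <- c(planted, setdiff(feature_ids(g$matrix), planted))
  data.frame(feature_id = ids, ri = rev(seq_along(ids)),
             stringsAsFactors = FALSE)
}

test_that("cross-validated subset evaluation is seeded and separable-exact", {
  g <- generate_synthetic(synth_config(3, 20, 20, 1, effect_size = 3,
                                       noise_sd = 0.3, seed = 2))
  feats <- unlist(g$truth$informative)
  spec <- classifier_spec("rf", seed = 4)
  r1 <- evaluate_subset(g$matrix, feats, spec, folds = 10, seed = 5)
  expect_equal(r1$mcc, 1.0)
  r2 <- evaluate_subset(g$matrix, feats, spec, folds = 10, seed = 5)
  expect_identical(attr(r1, "predictions"), attr(r2, "predictions"))
  expect_error(evaluate_subset(g$matrix, feats, spec, folds = 25, seed = 1),
               "fewer folds")
})

test_that("fold assignment is stratified", {
  labels <- rep(c("a", "b", "c"), times = c(12, 8, 20))
  f <- stratified_folds(labels, 4, seed = 3)
  expect_equal(sort(unique(f)), 1:4)
  for (cl in unique(labels)) {
    per_fold <- table(f[labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("a short ranked list clips the refinement window at the boundaries", {
  g <- generate_synthetic(synth_config(2, 10, 10, 1, effect_size = 2,
                                       seed = 3))
  ranked <- ranked_from_truth(g)
  res <- run_ifs(g$matrix, ranked,
                 ifs_config(step = 10, window = 10, folds = 5,
                            spec = classifier_spec("rf", seed = 1), seed = 2))
  expect_lte(res$optimal_size, 10L)
  expect_equal(res$curve$size, 1:10)       # stage 2 fills 1..10, no overshoot
  expect_equal(anyDuplicated(res$curve$size), 0L)
})

test_that("the reported optimum is the argmax of the emitted curve", {
  g <- generate_synthetic(synth_config(3, 12, 60, 3, effect_size = 1.5,
                                       seed = 6))
  res <- run_ifs(g$matrix, ranked_from_truth(g),
                 ifs_config(step = 5, window = 5, cap = 30, folds = 6,
                            spec = classifier_spec("rf", seed = 2), seed = 9))
  expect_equal(res$optimal_report$mcc, max(res$curve$mcc))
  smallest_max <- min(res$curve$size[res$curve$mcc == max(res$curve$mcc)])
  expect_equal(res$optimal_size, smallest_max)
  expect_identical(res$optimal_features,
                   ranked_from_truth(g)$feature_id[seq_len(res$optimal_size)])
  # the curve holds every evaluated size once; both stages share fold seeds,
  # so the coarse optimum re-evaluates identically in the refine window
  expect_equal(anyDuplicated(res$curve$size), 0L)
})

test_that("rerunning IFS under one seed reproduces the result", {
  g <- generate_synthetic(synth_config(3, 10, 40, 2, effect_size = 1.5,
                                       seed = 10))
  cfg <- ifs_config(step = 5, window = 3, cap = 20, folds = 5,
                    spec = classifier_spec("rf", seed = 7), seed = 11)
  expect_identical(run_ifs(g$matrix, ranked_from_truth(g), cfg)$curve,
                   run_ifs(g$matrix, ranked_from_truth(g), cfg)$curve)
})
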