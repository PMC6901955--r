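test_that("generated dimensions and ground truth follow the configuration", {
  cfg <- synth_config(n_classes = 6, samples_per_class = 40,
                      n_features = 1000, n_informative_per_class = 5,
                      effect_size = 1.5, noise_sd = 0.5, missing_rate = 0,
                      seed = 1)
  g <- generate_synthetic(cfg)
  expect_equal(dim(g$matrix), c(240L, 1000L))
  expect_equal(nlevels(g$matrix$labels), 6L)
  planted <- unlist(g$truth$informative)
  expect_length(planted, 30L)
  expect_false(anyDuplicated(planted) > 0)   # one class per planted feature
  expect_true(all(g$matrix$values > 0))
  expect_false(anyNA(g$matrix$values))
})

test_that("the same seed reproduces the matrix bit for bit", {
  cfg <- synth_config(3, 10, 50, 2, seed = 99, missing_rate = 0.1)
  g1 <- generate_synthetic(cfg)
  g2 <- generate_synthetic(cfg)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$truth, g2$truth)
})

test_that("planted features shift their class mean by the effect size", {
  cfg <- synth_config(4, 60, 200, 4, effect_size = 1.5, noise_sd = 0.5,
                      seed = 5)
  g <- generate_synthetic(cfg)
  lz <- log2(g$matrix$values)
  labs <- as.character(g$matrix$labels)
  for (cl in names(g$truth$informative)) {
    for (f in g$truth$informative[[cl]]) {
      diff <- mean(lz[labs == cl, f]) - mean(lz[labs != cl, f])
      se <- sqrt(0.5^2 / 60 + 0.5^2 / 180)
      expect_lt(abs(diff - 1.5), 3 * se)
    }
  }
})

test_that("a zero effect size plants no class association", {
  g <- generate_synthetic(synth_config(3, 30, 150, 3, effect_size = 0,
                                       noise_sd = 0.5, seed = 3))
  lz <- log2(g$matrix$values)
  labs <- as.character(g$matrix$labels)
  diffs <- vapply(unlist(g$truth$informative), function(f) {
    cl <- names(which(vapply(g$truth$informative, function(x) f %in% x,
                             logical(1))))
    mean(lz[labs == cl, f]) - mean(lz[labs != cl, f])
  }, numeric(1))
  expect_lt(max(abs(diffs)), 3 * sqrt(0.5^2 / 30 + 0.5^2 / 60))
})

test_that("the missing fraction tracks the configured rate", {
  g <- generate_synthetic(synth_config(3, 20, 400, 2, missing_rate = 0.08,
                                       seed = 12))
  frac <- mean(is.na(g$matrix$values))
  expect_lt(abs(frac - 0.08), 0.01)
})

test_that("invalid configurations are rejected by field name", {
  expect_error(synth_config(n_classes = 1), "n_classes")
  expect_error(synth_config(samples_per_class = 1), "samples_per_class")
  expect_error(synth_config(n_features = 10, n_informative_per_class = 3,
                            n_classes = 4), "n_informative_per_class")
  expect_error(synth_config(effect_size = -1), "effect_size")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
})
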