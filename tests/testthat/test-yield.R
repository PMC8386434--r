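test_that("density-minimum thresholds", {
  thr <- find_density_split(c(10, 11, 12, 40, 41, 42, 10.5, 11.5, 40.5, 41.5))
  expect_length(thr, 1)
  expect_gt(thr, 12); expect_lt(thr, 40)
  # bimodal mixture with a known valley near 30
  set.seed(1)
  y <- c(rnorm(100, 22, 2), rnorm(100, 38, 2))
  thr <- find_density_split(y)
  expect_gt(thr, 26); expect_lt(thr, 34)
  # trimodal: one threshold per gap
  set.seed(2)
  y3 <- c(rnorm(80, 15, 1.5), rnorm(80, 28, 1.5), rnorm(80, 41, 1.5))
  thr2 <- find_density_split(y3, n_thresholds = 2)
  expect_length(thr2, 2)
  expect_true(thr2[1] > 15 && thr2[1] < 28)
  expect_true(thr2[2] > 28 && thr2[2] < 41)
  # unimodal data cannot be split (regular normal quantiles: the KDE is
  # strictly unimodal, unlike a random draw which can carry double bumps)
  expect_error(find_density_split(qnorm(ppoints(200), 30, 2)), "mode")
  expect_error(find_density_split(c(1, 2)), "at least 10")
})

test_that("yield categorization boundary convention", {
  expect_equal(as.character(categorize_yield(c(30, 30.01), 30)),
               c("<=30", ">30"))
  lab3 <- categorize_yield(c(20, 30, 40), c(26, 35))
  expect_equal(as.character(lab3), c("<=26", "(26,35]", ">35"))
  lab4 <- categorize_yield(c(26, 35), c(20, 26, 35))
  expect_equal(as.character(lab4), c("(20,26]", "(26,35]"))
  expect_equal(nlevels(categorize_yield(1:5, numeric(0))), 1)
  expect_error(categorize_yield(1, c(35, 26)), "ascending")
})

test_that("feature assembly filters and completeness", {
  an <- cached_analysis()
  feats <- an$feats
  meta <- an$study$metadata
  keep <- meta$time_point %in% c("T0", "T1", "T2") & !is.na(meta$yield_t_ha)
  expect_equal(nrow(feats), sum(keep))
  expect_false(any(rownames(feats) %in%
                     meta$sample_id[meta$time_point == "T3"]))
  fc <- attr(feats, "feature_cols")
  expect_length(fc, 70 + 12 + 3)
  expect_false(anyNA(feats[, fc]))
  # missing property block is a hard error naming sample and feature
  props_bad <- an$props
  props_bad$fun_cooccurrence_transitivity[
    props_bad$sample_id == rownames(feats)[1]] <- NA
  expect_error(assemble_features(an$ord, props_bad, meta, an$thr),
               "fun_cooccurrence_transitivity")
})

test_that("probability forest is seeded, consistent and sane", {
  an <- cached_analysis()
  r1 <- fit_probability_forest(an$feats, n_trees = 100, seed = 42)
  r2 <- fit_probability_forest(an$feats, n_trees = 100, seed = 42)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$importance, r2$importance)
  # accuracy equals the confusion-matrix trace ratio and the direct mean
  expect_equal(r1$accuracy, mean(r1$predicted == r1$truth))
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  # stratified split sizes at 25%
  expect_equal(r1$n_train + r1$n_test, nrow(an$feats))
  expect_equal(r1$n_test / nrow(an$feats), 0.25, tolerance = 0.03)
  # probabilities are proper
  expect_true(all(abs(rowSums(r1$probabilities) - 1) < 1e-10))
  expect_error(fit_probability_forest(an$feats, n_trees = 10),
               "seed is mandatory")
})

test_that("constant features get exactly zero importance", {
  an <- cached_analysis()
  f <- an$feats
  f$dead_constant <- 1.0
  attr(f, "feature_cols") <- c(attr(an$feats, "feature_cols"),
                               "dead_constant")
  r <- fit_probability_forest(f, n_trees = 50, seed = 3)
  expect_identical(unname(r$importance[["dead_constant"]]), 0)
})

test_that("single-class training data is refused", {
  an <- cached_analysis()
  f <- an$feats
  f$label <- factor(rep("only", nrow(f)))
  expect_error(fit_probability_forest(f, seed = 1), "single class")
})

test_that("sensitivity schemes degrade and reduce to the base fit", {
  an <- cached_analysis()
  sens <- sensitivity_splits(an$feats, seed = 5, n_trees = 100)
  expect_equal(nrow(sens$comparison), 3)
  expect_equal(sens$comparison$n_categories, c(2, 3, 4))
  # one-threshold scheme is the plain fit
  base <- fit_probability_forest(an$feats, n_trees = 100, seed = 5)
  expect_identical(sens$reports$two_way$confusion, base$confusion)
  # a scheme placing everything in one class errors
  expect_error(sensitivity_splits(an$feats, schemes = list(allhigh = 500),
                                  seed = 1, n_trees = 10), "one class")
})

test_that("transitivity-yield regression", {
  # exactly linear, zero noise
  meta <- data.frame(sample_id = sprintf("s%d", 1:12),
                     block_id = rep(sprintf("b%d", 1:4), each = 3),
                     time_point = rep(c("T0", "T1", "T2"), 4),
                     yield_t_ha = rep(c(20, 25, 30, 35), each = 3))
  props <- data.frame(sample_id = meta$sample_id,
                      fun_cooccurrence_transitivity =
                        rep(c(0.1, 0.2, 0.3, 0.4), each = 3))
  r <- suppressWarnings(transitivity_yield_regression(props, meta))
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$slope, 50, tolerance = 1e-10)
  expect_equal(r$n, 4)
  # zero-variance predictor errors
  props$fun_cooccurrence_transitivity <- 0.2
  expect_error(transitivity_yield_regression(props, meta), "zero-variance")
  # planted positive slope is recovered on the yield-linked study
  an <- cached_analysis()
  rr <- transitivity_yield_regression(an$props, an$study$metadata)
  expect_gt(rr$slope, 0)
  expect_lt(rr$p_value, 0.05)
  # shuffled yields: association gone
  set.seed(4)
  meta_sh <- an$study$metadata
  blocks <- unique(meta_sh$block_id)
  yshuf <- setNames(sample(unique(meta_sh[!is.na(meta_sh$yield_t_ha),
                                          c("block_id", "yield_t_ha")])$yield_t_ha),
                    blocks)
  meta_sh$yield_t_ha <- unname(yshuf[meta_sh$block_id])
  r0 <- transitivity_yield_regression(an$props, meta_sh)
  expect_lt(r0$r_squared, 0.15)
})
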