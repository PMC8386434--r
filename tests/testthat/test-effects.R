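make_cell_meta <- function(n_per_cell = 2) {
  g <- expand.grid(rep_ = seq_len(n_per_cell),
                   treatment = c("control", "treated"),
                   time_point = c("T0", "T1"), stringsAsFactors = FALSE)
  g$sample_id <- sprintf("s%02d", seq_len(nrow(g)))
  g$location <- "L1"
  g
}

test_that("interaction estimate recovers the cell-mean geometry exactly", {
  meta <- make_cell_meta(2)
  cell_value <- function(trt, tp, means) means[[paste(trt, tp)]]
  # parallel changes: control 1 -> 2, treated 3 -> 4 => interaction 0
  means <- list("control T0" = 1, "control T1" = 2,
                "treated T0" = 3, "treated T1" = 4)
  v <- setNames(mapply(cell_value, meta$treatment, meta$time_point,
                       MoreArgs = list(means)), meta$sample_id)
  r <- interaction_contrast(v, meta, "L1", c("T0", "T1"))
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1)                       # flagged degenerate, est 0
  expect_equal(r$note, "degenerate")
  # forced interaction: control 1 -> 1, treated 1 -> 3 => exactly 2
  means <- list("control T0" = 1, "control T1" = 1,
                "treated T0" = 1, "treated T1" = 3)
  v <- setNames(mapply(cell_value, meta$treatment, meta$time_point,
                       MoreArgs = list(means)), meta$sample_id)
  r <- interaction_contrast(v, meta, "L1", c("T0", "T1"))
  expect_equal(r$estimate, 2)
})

test_that("interaction is invariant to additive time/group offsets", {
  meta <- make_cell_meta(4)
  set.seed(12)
  v <- setNames(rnorm(nrow(meta)), meta$sample_id)
  r0 <- interaction_contrast(v, meta, "L1", c("T0", "T1"))
  v2 <- v + 5 * (meta$time_point == "T1") - 3 * (meta$treatment == "treated")
  names(v2) <- meta$sample_id
  r2 <- interaction_contrast(v2, meta, "L1", c("T0", "T1"))
  expect_equal(r2$estimate, r0$estimate, tolerance = 1e-10)
  expect_equal(r2$p, r0$p, tolerance = 1e-10)
})

test_that("empty design cells are flagged untestable, not dropped", {
  meta <- make_cell_meta(2)
  meta <- meta[!(meta$treatment == "treated" & meta$time_point == "T1"), ]
  v <- setNames(seq_len(nrow(meta)), meta$sample_id)
  r <- interaction_contrast(v, meta, "L1", c("T0", "T1"))
  expect_equal(r$note, "untestable")
  expect_true(is.na(r$estimate))
})

test_that("BH step-up adjustment", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.031), 0.031)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # matches the reference implementation on random vectors, any order
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("type-I error of the interaction contrast is nominal", {
  meta <- make_cell_meta(5)
  set.seed(77)
  rej <- vapply(1:500, function(i) {
    v <- setNames(rnorm(nrow(meta)), meta$sample_id)
    interaction_contrast(v, meta, "L1", c("T0", "T1"))$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), 2 * se + 1e-12)
})

test_that("differential-abundance scan recovers planted interactions", {
  set.seed(21)
  n_otu <- 200; n_per_cell <- 5
  meta <- make_cell_meta(n_per_cell)
  planted <- sample(n_otu, 20)
  Y <- matrix(rnorm(nrow(meta) * n_otu, 0, 0.5), nrow(meta), n_otu,
              dimnames = list(meta$sample_id, sprintf("o%03d", 1:n_otu)))
  hit <- meta$treatment == "treated" & meta$time_point == "T1"
  Y[hit, planted] <- Y[hit, planted] + 2.0
  Y <- Y - rowMeans(Y)                       # valid CLR rows
  clr <- composition_matrix(Y, "clr")
  res <- differential_abundance_scan(clr, meta,
                                     intervals = list(c("T0", "T1")))
  flagged <- res$target[res$q < 0.05]
  planted_ids <- colnames(Y)[planted]
  expect_gte(mean(planted_ids %in% flagged), 0.8)
  if (length(flagged) > 0)
    expect_lte(mean(!(flagged %in% planted_ids)), 0.10)
  # single-OTU input agrees with a direct contrast
  one <- interaction_contrast(Y[, 1], meta, "L1", c("T0", "T1"),
                              target = colnames(Y)[1])
  row1 <- res[res$target == colnames(Y)[1], ]
  expect_equal(row1$estimate, one$estimate, tolerance = 1e-12)
  expect_equal(row1$p, one$p, tolerance = 1e-12)
})

test_that("property trajectory scan tabulates per property and interval", {
  an <- cached_analysis()
  res <- property_trajectory_scan(an$props, an$study$metadata,
                                  intervals = list(c("T0", "T1")))
  expect_equal(nrow(res), 12 * 3)            # 12 properties x 3 locations
  expect_true(all(res$direction %in% c("+", "-", "")))
  # constant values: estimate 0 and p 1, flagged
  props0 <- an$props
  props0$bac_cooccurrence_modularity <- 0.5
  res0 <- property_trajectory_scan(props0, an$study$metadata,
                                   intervals = list(c("T0", "T1")))
  r <- res0[res0$target == "bac_cooccurrence_modularity", ]
  expect_true(all(abs(r$estimate) < 1e-10))
  expect_true(all(r$p == 1))
  expect_true(all(r$note == "degenerate"))
})
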