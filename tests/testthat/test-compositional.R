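test_that("zero replacement follows the Dirichlet-posterior formula", {
  # counts (0, 10), alpha = (1/2, 1/2), s = 1: zero part gets
  # 0.5 * 1 / 11 = 1/22, nonzero part 1 * (1 - 1/22) = 21/22
  tab <- make_table(matrix(c(0L, 10L), 1))
  m <- replace_zeros(tab, alpha = c(0.5, 0.5), strength = 1)
  expect_equal(unname(m$values[1, ]), c(1 / 22, 21 / 22), tolerance = 1e-12)

  # no zeros: proportions unchanged
  m2 <- replace_zeros(make_table(matrix(c(3L, 7L), 1)))
  expect_equal(unname(m2$values[1, ]), c(0.3, 0.7), tolerance = 1e-12)

  # ratios among nonzero parts preserved exactly
  m3 <- replace_zeros(make_table(matrix(c(0L, 5L, 5L), 1)))
  expect_identical(m3$values[1, 2], m3$values[1, 3])

  # all-zero sample is named
  bad <- make_table(matrix(c(0L, 0L, 3L, 4L), 2, byrow = TRUE))
  expect_error(replace_zeros(bad), "s01")

  # replacement >= smallest observed proportion is warned about
  expect_warning(
    replace_zeros(make_table(matrix(c(0L, 1L, 9L), 1)),
                  alpha = c(0.8, 0.1, 0.1), strength = 20),
    "observed minimum")
})

test_that("zero replacement invariants hold on random tables", {
  set.seed(3)
  counts <- matrix(rpois(20 * 30, 2), 20, 30)
  counts[counts < 1] <- 0L
  counts[rowSums(counts) == 0, 1] <- 1L
  storage.mode(counts) <- "integer"
  tab <- make_table(counts)
  m <- replace_zeros(tab)
  expect_true(all(abs(rowSums(m$values) - 1) < 1e-10))
  expect_true(all(m$values > 0))
  # s -> 0 recovers the raw proportions of nonzero parts
  m0 <- replace_zeros(tab, strength = 1e-9)
  raw <- counts / rowSums(counts)
  expect_equal(m0$values[counts > 0], raw[counts > 0], tolerance = 1e-6)
})

test_that("CLR transform geometry", {
  m <- composition_matrix(matrix(c(0.25, 0.75), 1,
                                 dimnames = list("s1", c("a", "b"))),
                          "proportions")
  clr <- clr_transform(m)
  expect_equal(unname(clr$values[1, ]), c(-0.54931, 0.54931),
               tolerance = 1e-5)
  # uniform composition maps to zero
  u <- composition_matrix(matrix(1 / 4, 2, 4,
                                 dimnames = list(c("s1", "s2"),
                                                 letters[1:4])),
                          "proportions")
  expect_equal(max(abs(clr_transform(u)$values)), 0)
  # a clr-space matrix is not a valid input again
  expect_error(clr_transform(composition_matrix(
    matrix(c(-0.5, 0.5), 1, dimnames = list("s", c("a", "b"))), "clr")),
    "proportions")
})

test_that("CLR perturbation invariance", {
  set.seed(8)
  close_ <- function(x) x / sum(x)
  x <- close_(runif(6)); y <- close_(runif(6)); p <- runif(6, 0.1, 10)
  as_cm <- function(v) composition_matrix(
    matrix(v, 1, dimnames = list("s", letters[1:6])), "proportions")
  d0 <- clr_transform(as_cm(x))$values - clr_transform(as_cm(y))$values
  d1 <- clr_transform(as_cm(close_(x * p)))$values -
    clr_transform(as_cm(close_(y * p)))$values
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("Aitchison distance", {
  m <- composition_matrix(
    matrix(c(0.25, 0.75, 0.75, 0.25), 2, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("a", "b"))), "proportions")
  d <- aitchison_distance(clr_transform(m))
  expect_equal(d["s1", "s2"], log(3) * sqrt(2), tolerance = 1e-5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  # scale invariance of the raw composition
  tab1 <- make_table(matrix(c(2L, 6L, 6L, 2L), 2, byrow = TRUE))
  tab2 <- make_table(matrix(c(20L, 60L, 6L, 2L), 2, byrow = TRUE))
  d1 <- aitchison_distance(clr_transform(replace_zeros(tab1)))
  d2 <- aitchison_distance(clr_transform(replace_zeros(tab2)))
  expect_equal(d1[1, 2], d2[1, 2], tolerance = 1e-12)
})

test_that("PCoA classical scaling", {
  # three collinear points: one positive eigenvalue, second ~ 0
  d <- as.matrix(dist(c(0, 1, 2)))
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ord <- pcoa(d, 3)
  expect_gt(ord$eigenvalues[1], 1)
  expect_lt(abs(ord$eigenvalues[2]), 1e-10)
  # duplicated sample gets identical coordinates
  d4 <- as.matrix(dist(c(0, 1, 2, 2)))
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  ord4 <- pcoa(d4, 2)
  expect_equal(ord4$scores["c", ], ord4$scores["d", ], tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA on Aitchison equals PCA on centered CLR", {
  st <- cached_study("tiny")
  clr <- clr_transform(replace_zeros(st$fungi))
  ev_pcoa <- pcoa(aitchison_distance(clr), 5)$eigenvalues
  Xc <- scale(clr$values, center = TRUE, scale = FALSE)
  ev_pca <- svd(Xc)$d^2
  k <- min(length(ev_pca), sum(ev_pcoa > 1e-8))
  expect_equal(ev_pcoa[1:k], ev_pca[1:k], tolerance = 1e-8)
})

test_that("joint projection is a centered SVD", {
  st <- cached_study("tiny")
  clr16 <- clr_transform(replace_zeros(st$bacteria))
  clrIT <- clr_transform(replace_zeros(st$fungi))
  expect_message(ord <- joint_projection(clr16, clrIT, 70), "rank")
  # n = 8 samples: rank at most 7
  expect_lte(ncol(ord$scores), 7)
  expect_true(all(diff(ord$eigenvalues[seq_len(ncol(ord$scores))]) <= 1e-12))
  # full-rank reconstruction of the centered concatenated matrix
  X <- cbind(clr16$values, clrIT$values[rownames(clr16$values), ])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  rec <- ord$scores %*% t(ord$loadings)
  expect_equal(rec, Xc, tolerance = 1e-8, ignore_attr = TRUE)
  # mismatched samples are reported
  clr_bad <- composition_matrix(clrIT$values[-1, , drop = FALSE], "clr")
  expect_error(joint_projection(clr16, clr_bad), "sample sets differ")
})
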