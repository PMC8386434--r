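#' Composition matrices
#'
#' Thin container tagging a real samples x OTUs matrix with the space it lives
#' in: `proportions` (strictly positive rows summing to 1) or `clr` (rows
#' summing to 0 after the centered log-ratio transform).
#'
#' @param values numeric matrix with dimnames.
#' @param space `"proportions"` or `"clr"`.
#' @return object of class `composition_matrix`.
#' @export
composition_matrix <- function(values, space = c("proportions", "clr")) {
  space <- match.arg(space)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  rs <- rowSums(values)
  if (space == "proportions") {
    if (any(values <= 0)) stop("proportions must be strictly positive")
    if (any(abs(rs - 1) > 1e-10)) stop("proportion rows must sum to 1")
  } else if (any(abs(rs) > 1e-8 * pmax(1, ncol(values)))) {
    stop("clr rows must sum to 0")
  }
  structure(list(values = values, space = space), class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix [%s]: %d samples x %d parts\n", x$space,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts with posterior-expected small proportions under a
#' Dirichlet prior and multiplicatively shrinks the nonzero parts so that each
#' row still sums to one. For a sample with total count n, a zero part j
#' becomes `alpha_j * s / (n + s)`; nonzero parts are rescaled by
#' `1 - sum_zeros(alpha_k * s / (n + s))`, which preserves all ratios among
#' the observed parts exactly.
#'
#' @param table an [otu_table].
#' @param alpha per-part prior means, summing to 1; default symmetric `1/D`.
#' @param strength total prior mass s > 0; default `D/2`, i.e. a Jeffreys-style
#'   pseudo-count of 0.5 per part.
#' @return [composition_matrix] in `proportions` space. A warning is raised if
#'   any imputed value is at least as large as the smallest observed nonzero
#'   proportion in its sample.
#' @export
replace_zeros <- function(table, alpha = NULL, strength = NULL) {
  stopifnot(inherits(table, "otu_table"))
  x <- table$counts
  D <- ncol(x)
  if (is.null(alpha)) alpha <- rep(1 / D, D)
  if (length(alpha) != D) stop("alpha must have one entry per OTU")
  if (any(alpha <= 0) || abs(sum(alpha) - 1) > 1e-8)
    stop("alpha must be positive and sum to 1")
  if (is.null(strength)) strength <- D / 2
  if (strength <= 0) stop("strength must be > 0")
  n <- rowSums(x)
  if (any(n == 0))
    stop("sample with all-zero counts: ", rownames(x)[which(n == 0)][1L])
  out <- matrix(0, nrow(x), D, dimnames = dimnames(x))
  squeeze <- FALSE
  for (i in seq_len(nrow(x))) {
    zeros <- x[i, ] == 0L
    imput <- alpha * strength / (n[i] + strength)
    if (any(zeros)) {
      shrink <- 1 - sum(imput[zeros])
      out[i, zeros] <- imput[zeros]
      out[i, !zeros] <- (x[i, !zeros] / n[i]) * shrink
      if (any(x[i, ] > 0) &&
          max(imput[zeros]) >= min(x[i, !zeros] / n[i]))
        squeeze <- TRUE
    } else {
      out[i, ] <- x[i, ] / n[i]
    }
  }
  if (squeeze)
    warning("zero replacement at least as large as an observed minimum proportion; consider a weaker prior")
  composition_matrix(out, "proportions")
}

#' Centered log-ratio transform
#'
#' `clr(p)_j = log(p_j) - mean_k log(p_k)`; every row of the result sums to 0.
#'
#' @param m [composition_matrix] in `proportions` space (all entries > 0);
#'   zero replacement must precede this step.
#' @return [composition_matrix] in `clr` space.
#' @export
clr_transform <- function(m) {
  stopifnot(inherits(m, "composition_matrix"))
  if (m$space != "proportions") stop("expected a proportions matrix")
  if (any(m$values <= 0))
    stop("nonpositive entry; run replace_zeros() first")
  lg <- log(m$values)
  composition_matrix(lg - rowMeans(lg), "clr")
}

#' Aitchison distance matrix
#'
#' Euclidean distance between CLR-transformed compositions; invariant to
#' rescaling of the raw counts of any sample.
#'
#' @param m [composition_matrix] in `clr` space.
#' @return symmetric numeric matrix with zero diagonal and sample-id dimnames.
#' @export
aitchison_distance <- function(m) {
  stopifnot(inherits(m, "composition_matrix"))
  if (m$space != "clr") stop("expected a clr matrix")
  as.matrix(stats::dist(m$values, method = "euclidean"))
}

#' Principal-coordinate analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it. Axes are
#' restricted to positive eigenvalues; negative eigenvalues are reported for
#' diagnostic purposes. On an Aitchison distance matrix the positive
#' eigenvalues equal those of a PCA of the centered CLR matrix.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_axes maximum number of axes to return.
#' @return object of class `ordination`: list with `scores` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `axis_labels`, `loadings` (`NULL`
#'   for PCoA).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  G <- gower_center(d)
  eg <- eigen(G, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values) * 1e-12 & eg$values > 0)
  k <- min(n_axes, length(pos))
  scores <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eg$values[pos[seq_len(k)]]), k, k)
  rownames(scores) <- rownames(d)
  labs <- paste0("PCo", seq_len(k))
  colnames(scores) <- labs
  structure(list(scores = scores, eigenvalues = eg$values,
                 axis_labels = labs, loadings = NULL,
                 method = "pcoa"), class = "ordination")
}

# Gower double-centering of a distance matrix: G = -(1/2) C d^2 C.
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
}

#' Joint PCA projection of two CLR matrices
#'
#' Column-concatenates the CLR matrices of the two marker domains over a
#' shared sample set, column-centers (no unit-variance scaling) and takes the
#' SVD. Used to build the compositional block of the yield feature table
#' (default 70 components).
#'
#' @param clr_16s,clr_its [composition_matrix] objects in `clr` space with
#'   identical sample sets.
#' @param n_components requested number of components; silently truncated to
#'   the matrix rank (with a message).
#' @return `ordination` with `scores`, `loadings`, `eigenvalues`
#'   (variances of each component, non-increasing) and `axis_labels`
#'   (`PC1`, `PC2`, ...).
#' @export
joint_projection <- function(clr_16s, clr_its, n_components = 70) {
  stopifnot(inherits(clr_16s, "composition_matrix"),
            inherits(clr_its, "composition_matrix"))
  if (clr_16s$space != "clr" || clr_its$space != "clr")
    stop("both matrices must be in clr space")
  s1 <- rownames(clr_16s$values); s2 <- rownames(clr_its$values)
  if (!setequal(s1, s2) || length(s1) != length(s2)) {
    diffs <- c(setdiff(s1, s2), setdiff(s2, s1))
    stop("sample sets differ between markers: ",
         paste(utils::head(diffs, 5), collapse = ", "))
  }
  X <- cbind(clr_16s$values, clr_its$values[s1, , drop = FALSE])
  colnames(X) <- c(paste0("16S|", colnames(clr_16s$values)),
                   paste0("ITS|", colnames(clr_its$values)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(n_components, rank)
  if (k < n_components)
    message(sprintf("joint_projection: rank %d < requested %d components",
                    rank, n_components))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  labs <- paste0("PC", seq_len(k))
  dimnames(scores) <- list(rownames(Xc), labs)
  dimnames(loadings) <- list(colnames(X), labs)
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = sv$d^2 / max(1, nrow(Xc) - 1),
                 axis_labels = labs, method = "pca"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination [%s]: %d samples, %d axes\n", x$method,
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
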