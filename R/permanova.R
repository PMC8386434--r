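#' Permutational multivariate analysis of variance (distance-based)
#'
#' Partitions the total sum of squares of a distance matrix among an ordered
#' list of design factors (sequential, Type I, in the order given) using
#' Gower's double-centered inner-product matrix and projection ("hat")
#' matrices, and tests each term's pseudo-F by unrestricted permutation of
#' sample identities. `R^2 = SS_term / SS_total`; the term and residual `R^2`
#' sum to 1 by construction. Interaction terms (`a:b`) are supported.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param meta data.frame with a `sample_id` column and every factor named in
#'   `terms`; reordered internally to match `d`.
#' @param terms ordered character vector of model terms, e.g.
#'   `c("location", "time_point", "treatment")` or `"location:variety"`.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame of class `permanova` with one row per term plus
#'   `Residual` and `Total` rows: `term`, `df`, `ss`, `r2`, `f`, `p`.
#'   Confounded (aliased) terms are reported with `df = 0` and `NA` tests.
#' @export
permanova <- function(d, meta, terms, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs sample-id dimnames")
  if (!all(ids %in% meta$sample_id))
    stop("metadata missing sample(s): ",
         paste(utils::head(setdiff(ids, meta$sample_id), 5), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  n <- nrow(d)
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  # sequential hat-matrix differences, one per term
  data_env <- as.data.frame(lapply(meta, function(col) {
    if (is.character(col)) col <- factor(col)
    if (is.factor(col)) {
      col <- droplevels(col)
      # single-level factor: no contrast exists; a zero column keeps the
      # term in the table with 0 df instead of erroring
      if (nlevels(col) < 2L) col <- rep(0, length(col))
    }
    col
  }))
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  Hd <- list(); dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(k)],
                                              collapse = " + ")))
    X <- stats::model.matrix(fml, data = data_env)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    H <- tcrossprod(Q)
    Hd[[k]] <- H - H_prev
    dfs[k] <- qx$rank - rank_prev
    H_prev <- H; rank_prev <- qx$rank
  }
  df_res <- n - rank_prev
  ss <- vapply(Hd, function(h) sum(h * G), numeric(1))
  ss_res <- ss_total - sum(ss)
  ms_res <- ss_res / df_res
  f_obs <- ifelse(dfs > 0, (ss / pmax(dfs, 1)) / ms_res, NA_real_)

  # permutation of sample identities = joint row/col permutation of G
  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    ssb <- vapply(Hd, function(h) sum(h * Gp), numeric(1))
    msb_res <- (ss_total - sum(ssb)) / df_res
    fb <- (ssb / pmax(dfs, 1)) / msb_res
    exceed <- exceed + (fb >= f_obs - 1e-12)
  }
  pvals <- ifelse(dfs > 0, (1 + exceed) / (1 + n_perm), NA_real_)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    ss = c(ss, ss_res, ss_total),
    r2 = c(ss, ss_res, ss_total) / ss_total,
    f = c(f_obs, NA_real_, NA_real_),
    p = c(pvals, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  out
}
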