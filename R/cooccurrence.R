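#' Presence/absence incidence matrix
#'
#' Presence is defined on the raw counts (`count > 0`), before any zero
#' replacement: the pairwise co-occurrence model is incidence-based and
#' replacement would destroy the zeros it tests.
#'
#' @param table an [otu_table].
#' @return integer 0/1 matrix, samples x OTUs.
#' @export
incidence_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  inc <- (table$counts > 0L) * 1L
  dimnames(inc) <- dimnames(table$counts)
  inc
}

#' Prevalence filter for network construction
#'
#' Keeps OTUs detected in at least `min_prevalence_fraction` of all samples
#' (30% for bacteria and 10% for fungi in the reference analysis). If more
#' than `max_otus` survive, the most prevalent `max_otus` are kept, with ties
#' broken by total count and then OTU id; the kept set is further capped so
#' that the number of unordered pairs does not exceed `max_pairs`.
#'
#' @param incidence binary matrix from [incidence_matrix()].
#' @param min_prevalence_fraction prevalence threshold in (0, 1).
#' @param max_otus hard cap on retained OTUs (default 4000).
#' @param max_pairs cap on `choose(kept, 2)` (default 1e7).
#' @param total_counts optional per-OTU total counts used for tie-breaking;
#'   zero when omitted.
#' @return character vector of retained OTU ids, ordered by the ranking.
#' @export
filter_otus <- function(incidence, min_prevalence_fraction,
                        max_otus = 4000, max_pairs = 1e7,
                        total_counts = NULL) {
  if (min_prevalence_fraction <= 0 || min_prevalence_fraction >= 1)
    stop("min_prevalence_fraction must be in (0, 1)")
  prev <- colSums(incidence)
  n <- nrow(incidence)
  keep <- which(prev / n >= min_prevalence_fraction)
  if (!length(keep))
    stop("no OTU passes the prevalence threshold ", min_prevalence_fraction,
         "; lower the threshold")
  if (is.null(total_counts)) total_counts <- rep(0, ncol(incidence))
  ids <- colnames(incidence)[keep]
  ord <- order(-prev[keep], -total_counts[keep], ids)
  ids <- ids[ord]
  # pair cap implies an OTU cap: choose(m, 2) <= max_pairs
  pair_cap <- floor((1 + sqrt(1 + 8 * max_pairs)) / 2)
  ids[seq_len(min(length(ids), max_otus, pair_cap))]
}

#' Exact pairwise co-occurrence tail probabilities
#'
#' Under the null that the `N1` and `N2` occupied samples of two OTUs are
#' placed independently and uniformly among the `N` samples, the number of
#' shared samples X is hypergeometric:
#' `P(X = j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)`. Both inclusive tails
#' are returned (`p_gt = P(X >= j_obs)`, `p_lt = P(X <= j_obs)`), evaluated
#' in log space, together with the null expectation `N1 N2 / N`.
#'
#' All arguments are vectorized.
#'
#' @param N number of samples.
#' @param N1,N2 incidence counts of the two OTUs.
#' @param j_obs observed co-occurrence count; must lie in the support
#'   `max(0, N1 + N2 - N) .. min(N1, N2)`.
#' @return data.frame with `N`, `N1`, `N2`, `j_obs`, `expected_j`, `p_lt`,
#'   `p_gt`.
#' @export
veech_pair_test <- function(N, N1, N2, j_obs) {
  len <- max(length(N), length(N1), length(N2), length(j_obs))
  N <- rep_len(N, len); N1 <- rep_len(N1, len)
  N2 <- rep_len(N2, len); j_obs <- rep_len(j_obs, len)
  if (any(N1 < 0 | N2 < 0 | N1 > N | N2 > N))
    stop("need 0 <= N1, N2 <= N")
  lo <- pmax(0, N1 + N2 - N); hi <- pmin(N1, N2)
  if (any(j_obs < lo | j_obs > hi))
    stop("j_obs outside the hypergeometric support (upstream bug?)")
  # inclusive tails: P(X <= j) and P(X >= j) = 1 - P(X <= j - 1)
  p_lt <- stats::phyper(j_obs, N1, N - N1, N2)
  p_gt <- stats::phyper(j_obs - 1, N1, N - N1, N2, lower.tail = FALSE)
  data.frame(N = N, N1 = N1, N2 = N2, j_obs = j_obs,
             expected_j = N1 * N2 / N,
             p_lt = pmin(1, p_lt), p_gt = pmin(1, p_gt))
}

empty_edges <- function() {
  data.frame(otu_a = character(), otu_b = character(),
             edge_type = character(), p_lt = numeric(), p_gt = numeric(),
             observed_j = integer(), expected_j = numeric(),
             stringsAsFactors = FALSE)
}

#' Metacommunity network object
#'
#' @param nodes retained OTU ids (isolated nodes included).
#' @param edges data.frame of classified edges with their pair-test fields.
#' @param marker marker domain label.
#' @param params filter provenance (`n_samples`, `min_prevalence`,
#'   `max_otus`, `alpha`).
#' @param abundance_fraction fraction of total sample abundance captured by
#'   the node set (`NA` if counts were not supplied).
#' @return object of class `metacommunity_network`.
#' @export
metacommunity_network <- function(nodes, edges, marker = "16S",
                                  params = list(), abundance_fraction = NA_real_) {
  stopifnot(all(edges$otu_a %in% nodes), all(edges$otu_b %in% nodes),
            !any(edges$otu_a == edges$otu_b))
  structure(list(nodes = nodes, edges = edges, marker = marker,
                 params = params, abundance_fraction = abundance_fraction),
            class = "metacommunity_network")
}

#' @export
print.metacommunity_network <- function(x, ...) {
  cat(sprintf(
    "metacommunity_network [%s]: %d nodes, %d cooccurrence + %d coexclusion edges\n",
    x$marker, length(x$nodes), sum(x$edges$edge_type == "cooccurrence"),
    sum(x$edges$edge_type == "coexclusion")))
  invisible(x)
}

#' Build the metacommunity co-occurrence / co-exclusion network
#'
#' Tests every unordered pair of retained OTUs with [veech_pair_test()] over
#' all samples jointly. A pair is a co-occurrence edge iff `p_gt < alpha` and
#' the observed count exceeds expectation, a co-exclusion edge iff
#' `p_lt < alpha` and the observed count is below expectation; everything
#' else is "random". Requiring the observed count on the correct side of the
#' expectation prevents a degenerate pair being classified both ways.
#'
#' @param incidence binary matrix, samples x OTUs.
#' @param kept_otus ids from [filter_otus()] (subset of the columns).
#' @param alpha significance level for each inclusive tail (default 0.05,
#'   no multiple-testing correction, matching the reference convention).
#' @param marker marker label stored on the network.
#' @param counts optional raw count matrix (same shape as `incidence`) used to
#'   report the fraction of total abundance captured by the node set.
#' @param min_prevalence,max_otus provenance fields recorded on the network.
#' @return a [metacommunity_network].
#' @export
build_metacommunity <- function(incidence, kept_otus, alpha = 0.05,
                                marker = "16S", counts = NULL,
                                min_prevalence = NA_real_, max_otus = 4000) {
  if (!all(kept_otus %in% colnames(incidence)))
    stop("kept_otus must be columns of the incidence matrix")
  X <- incidence[, kept_otus, drop = FALSE]
  N <- nrow(X)
  m <- ncol(X)
  edges <- empty_edges()
  if (m >= 2L && alpha > 0) {
    J <- crossprod(X)               # m x m matrix of shared-sample counts
    prev <- diag(J)
    ut <- which(upper.tri(J), arr.ind = TRUE)
    pt <- veech_pair_test(N, prev[ut[, 1L]], prev[ut[, 2L]], J[ut])
    co  <- pt$p_gt < alpha & pt$j_obs > pt$expected_j
    cx  <- pt$p_lt < alpha & pt$j_obs < pt$expected_j
    sel <- co | cx
    if (any(sel)) {
      edges <- data.frame(
        otu_a = kept_otus[ut[sel, 1L]],
        otu_b = kept_otus[ut[sel, 2L]],
        edge_type = ifelse(co[sel], "cooccurrence", "coexclusion"),
        p_lt = pt$p_lt[sel], p_gt = pt$p_gt[sel],
        observed_j = as.integer(pt$j_obs[sel]),
        expected_j = pt$expected_j[sel],
        stringsAsFactors = FALSE)
    }
  }
  ab <- NA_real_
  if (!is.null(counts)) {
    tot <- rowSums(counts)
    cap <- rowSums(counts[, kept_otus, drop = FALSE])
    ab <- mean(cap / pmax(1, tot))
  }
  metacommunity_network(
    nodes = kept_otus, edges = edges, marker = marker,
    params = list(n_samples = N, min_prevalence = min_prevalence,
                  max_otus = max_otus, alpha = alpha),
    abundance_fraction = ab)
}
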