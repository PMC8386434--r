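#' Per-sample alpha diversity
#'
#' Richness is the number of OTUs with a nonzero count; Shannon H' is
#' `-sum p_j log p_j` in nats over the nonzero parts, so `H' <= log(richness)`
#' with equality for a uniform composition.
#'
#' @param table an [otu_table].
#' @return data.frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  x <- table$counts
  n <- rowSums(x)
  if (any(n == 0))
    warning("all-zero sample(s): ",
            paste(rownames(x)[n == 0], collapse = ", "),
            "; richness and Shannon set to 0")
  rich <- rowSums(x > 0)
  shan <- vapply(seq_len(nrow(x)), function(i) {
    if (n[i] == 0) return(0)
    p <- x[i, x[i, ] > 0] / n[i]
    -sum(p * log(p))
  }, numeric(1))
  data.frame(sample_id = rownames(x), richness = as.integer(rich),
             shannon = shan, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Mid-ranks for ties; exact two-sided p-value when the combined sample size
#' is at most 20 and there are no ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param values_a,values_b numeric vectors, each nonempty.
#' @return list with `statistic` (Mann-Whitney U for the first group) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be nonempty")
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  ex <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = "two.sided",
    exact = ex, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Z-score normalization within groups
#'
#' @param values numeric vector.
#' @param grouping factor/vector of the same length; within each group the
#'   result has mean 0 and sd 1 (denominator n - 1).
#' @return numeric vector in the original order.
#' @export
zscore_by_group <- function(values, grouping) {
  stopifnot(length(values) == length(grouping))
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 2L) stop("group '", g, "' has fewer than 2 values")
    s <- stats::sd(values[idx])
    if (!is.finite(s) || s == 0) stop("group '", g, "' has zero variance")
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Time-trajectory contrasts of alpha diversity
#'
#' Z-scores each metric within location, then fits a one-way ANOVA on
#' time point and reports the pairwise contrast of every later time point
#' against the reference (default T0): estimate (difference of means on the
#' Z scale), t statistic, and two-sided p.
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param meta validated metadata (rows matched by `sample_id`).
#' @param reference reference time point, default `"T0"`.
#' @param metrics columns of `alpha` to test.
#' @return data.frame with one row per metric x contrast.
#' @export
time_effect_tests <- function(alpha, meta, reference = "T0",
                              metrics = c("richness", "shannon")) {
  m <- merge(alpha, meta, by = "sample_id")
  tps <- sort(unique(m$time_point))
  if (!reference %in% tps) stop("reference time point absent: ", reference)
  out <- list()
  for (metric in metrics) {
    z <- zscore_by_group(as.numeric(m[[metric]]), m$location)
    tp <- stats::relevel(factor(m$time_point, levels = tps), ref = reference)
    fit <- stats::lm(z ~ tp)
    cf <- summary(fit)$coefficients
    for (other in setdiff(tps, reference)) {
      nm <- paste0("tp", other)
      if (!nm %in% rownames(cf)) {
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, contrast = paste0(reference, " vs ", other),
          estimate = NA_real_, t = NA_real_, p = NA_real_,
          note = "missing time point", stringsAsFactors = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, contrast = paste0(reference, " vs ", other),
        estimate = cf[nm, 1L], t = cf[nm, 3L], p = cf[nm, 4L], note = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genus-level composition summary
#'
#' Aggregates counts by the genus field of the taxonomy lineage (rank 6 of
#' the 7-rank semicolon convention; empty genus becomes `"unclassified"`) and
#' returns per-sample relative abundances of the top `k` genera by overall
#' mean abundance.
#'
#' @param table an [otu_table] with taxonomy.
#' @param k number of genera to keep (all if fewer exist).
#' @return matrix genera x samples of relative abundances.
#' @export
top_genera <- function(table, k = 15) {
  stopifnot(inherits(table, "otu_table"))
  ranks <- strsplit(table$taxonomy, ";", fixed = TRUE)
  genus <- vapply(ranks, function(r) {
    g <- if (length(r) >= 6L) trimws(r[[6L]]) else ""
    if (!nzchar(g)) "unclassified" else g
  }, character(1))
  x <- table$counts
  rel <- x / pmax(1, rowSums(x))
  agg <- rowsum(t(rel), group = genus)   # genera x samples
  ord <- order(rowMeans(agg), decreasing = TRUE)
  agg[ord[seq_len(min(k, nrow(agg)))], , drop = FALSE]
}
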