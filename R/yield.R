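#' Density-minimum yield thresholds
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
#' `bw.nrd0`) to the block-level yields and returns the deepest local density
#' minimum in each gap between the `n_thresholds + 1` highest modes — the
#' "zero-probability density point" convention used to binarize a bimodal
#' yield distribution.
#'
#' @param yields numeric vector of block yields (t/ha), length >= 10.
#' @param n_thresholds number of thresholds (1 for a two-way split).
#' @return numeric vector of thresholds, ascending.
#' @export
find_density_split <- function(yields, n_thresholds = 1) {
  yields <- yields[!is.na(yields)]
  if (length(yields) < 10) stop("need at least 10 yield values")
  den <- stats::density(yields, bw = "nrd0")
  y <- den$y; x <- den$x
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              FALSE)
  is_min <- c(FALSE, y[2:(k - 1)] < y[1:(k - 2)] & y[2:(k - 1)] <= y[3:k],
              FALSE)
  modes <- which(is_max)
  # ignore negligible tail wiggles of the KDE: a bump under 5% of the peak
  # density is numerical noise, not a mode
  modes <- modes[y[modes] >= 0.05 * max(y)]
  if (length(modes) < n_thresholds + 1)
    stop("density has ", length(modes), " mode(s); cannot place ",
         n_thresholds, " threshold(s) — supply an explicit threshold instead")
  top <- modes[order(y[modes], decreasing = TRUE)][seq_len(n_thresholds + 1)]
  top <- sort(top)
  thr <- vapply(seq_len(n_thresholds), function(g) {
    mins <- which(is_min)
    mins <- mins[mins > top[g] & mins < top[g + 1]]
    if (!length(mins))
      stop("no density minimum between modes at ",
           format(x[top[g]]), " and ", format(x[top[g + 1]]))
    x[mins[which.min(y[mins])]]
  }, numeric(1))
  sort(thr)
}

#' Categorize yields at fixed thresholds
#'
#' Left-closed convention: a value exactly on a threshold belongs to the lower
#' category (`<=30 t/ha` vs `>30 t/ha`).
#'
#' @param yields numeric vector.
#' @param thresholds ascending numeric vector; empty for a single category.
#' @return factor of category labels, e.g. `"<=30"`, `"(26,35]"`, `">35"`.
#' @export
categorize_yield <- function(yields, thresholds) {
  if (!length(thresholds))
    return(factor(rep("all", length(yields)), levels = "all"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  thr <- format(thresholds, trim = TRUE, digits = 6)
  # labels: <=t1, (t1,t2], ..., >tk
  labs <- paste0("<=", thr[1L])
  if (length(thr) > 1L)
    labs <- c(labs, paste0("(", thr[-length(thr)], ",", thr[-1L], "]"))
  labs <- c(labs, paste0(">", thr[length(thr)]))
  cut(yields, breaks = c(-Inf, thresholds, Inf), labels = labs, right = TRUE)
}

#' Assemble the yield-model feature table
#'
#' One row per sample at T0-T2 with a known block yield: the joint PC scores,
#' the 12 local network properties, a treatment indicator, a soil-type
#' indicator (bulk vs rhizosphere) and a single categorical `geo_variety`
#' factor collapsing location and seed variety, plus the yield-category label.
#' T3 samples and samples with missing yield are excluded by design.
#'
#' @param ordination [joint_projection()] result (scores used as features).
#' @param props [properties_table()] output.
#' @param meta validated metadata.
#' @param thresholds yield-category thresholds for [categorize_yield()].
#' @return data.frame with numeric feature columns and a `label` factor;
#'   attribute `feature_cols` lists the feature column names.
#' @export
assemble_features <- function(ordination, props, meta, thresholds) {
  keep <- meta$time_point %in% c("T0", "T1", "T2") & !is.na(meta$yield_t_ha)
  m <- meta[keep, , drop = FALSE]
  miss <- setdiff(m$sample_id, rownames(ordination$scores))
  if (length(miss))
    stop("sample '", miss[1L], "' missing from the ordination scores")
  prop_cols <- grep("^(bac|fun)_(cooccurrence|coexclusion)_", names(props),
                    value = TRUE)
  pr <- props[match(m$sample_id, props$sample_id), prop_cols, drop = FALSE]
  if (anyNA(pr)) {
    bad <- which(is.na(pr), arr.ind = TRUE)[1L, ]
    stop(sprintf("sample '%s' lacks feature '%s'", m$sample_id[bad[1L]],
                 prop_cols[bad[2L]]))
  }
  sc <- ordination$scores[m$sample_id, , drop = FALSE]
  geo <- factor(paste(m$location, m$variety, sep = "|"))
  out <- data.frame(sc, pr,
                    treatment = as.integer(m$treatment == "treated"),
                    soil_rhizosphere = as.integer(m$soil_type == "rhizosphere"),
                    geo_variety = as.integer(geo),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- m$sample_id
  out$label <- categorize_yield(m$yield_t_ha, thresholds)
  attr(out, "feature_cols") <- setdiff(names(out), "label")
  attr(out, "yield") <- stats::setNames(m$yield_t_ha, m$sample_id)
  attr(out, "block_id") <- stats::setNames(m$block_id, m$sample_id)
  out
}

#' Fit a probability forest and evaluate it on a held-out split
#'
#' A stratified train/test split at `test_fraction`, a forest of CART trees
#' whose terminal-node class frequencies are averaged into class
#' probabilities, arg-max labels, the confusion matrix, accuracy and the
#' Gini (mean decrease in impurity) importance ranking. Fully reproducible
#' given `seed`.
#'
#' @param features output of [assemble_features()] (or any data.frame of
#'   numeric features plus a `label` factor).
#' @param test_fraction held-out fraction (default 0.25).
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node_size minimal node size still eligible for splitting.
#' @param seed RNG seed (mandatory).
#' @return object of class `forest_report`: list with `confusion`,
#'   `accuracy`, `importance` (sorted, named), `probabilities`, `predicted`,
#'   `truth`, `train_ids`, `test_ids`, `n_train`, `n_test`, `seed`.
#' @export
fit_probability_forest <- function(features, test_fraction = 0.25,
                                   n_trees = 500, mtry = NULL,
                                   min_node_size = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  fcols <- attr(features, "feature_cols")
  if (is.null(fcols)) fcols <- setdiff(names(features), "label")
  X <- as.matrix(features[, fcols, drop = FALSE])
  storage.mode(X) <- "double"
  label <- droplevels(factor(features$label))
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(label)) {
    idx <- which(label == cl)
    n_test_cl <- round(test_fraction * length(idx))
    test_idx <- c(test_idx, sample(idx, n_test_cl))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(X)), test_idx)
  y_train <- label[train_idx]
  if (nlevels(droplevels(y_train)) < 2L)
    stop("training data contain a single class; cannot fit a classifier")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- .forest_fit_cpp(X[train_idx, , drop = FALSE],
                         as.integer(label[train_idx]) - 1L,
                         nlevels(label), as.integer(n_trees),
                         as.integer(mtry), as.integer(min_node_size))
  probs <- .forest_predict_cpp(fit, X[test_idx, , drop = FALSE])
  colnames(probs) <- levels(label)
  rownames(probs) <- rownames(X)[test_idx]
  pred <- factor(levels(label)[max.col(probs, ties.method = "first")],
                 levels = levels(label))
  truth <- label[test_idx]
  confusion <- table(truth = truth, predicted = pred)
  importance <- stats::setNames(fit$importance, fcols)
  importance <- sort(importance, decreasing = TRUE)
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    importance = importance,
    probabilities = probs, predicted = pred, truth = truth,
    train_ids = rownames(X)[train_idx], test_ids = rownames(X)[test_idx],
    n_train = length(train_idx), n_test = length(test_idx),
    n_trees = n_trees, mtry = mtry, seed = seed,
    model = fit, feature_cols = fcols), class = "forest_report")
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("probability forest: %d train / %d test, accuracy %.3f\n",
              x$n_train, x$n_test, x$accuracy))
  cat("top importances:\n")
  print(round(utils::head(x$importance, 6), 4))
  invisible(x)
}

#' Category-scheme sensitivity analysis of the yield model
#'
#' Refits the probability forest under alternative yield categorizations
#' (by default: the two-way density-minimum split plus the fixed three-way
#' (26, 35) and four-way (20, 26, 35) schemes) and compares Gini importance
#' ranks, in particular whether fungal co-occurrence transitivity outranks
#' the geography/variety factor.
#'
#' @param features output of [assemble_features()] (any scheme; yields are
#'   re-categorized from the stored per-sample yields).
#' @param schemes named list of threshold vectors.
#' @param seed RNG seed passed to every fit.
#' @param n_trees trees per forest.
#' @return list with `reports` (one `forest_report` per scheme) and
#'   `comparison` data.frame (`scheme`, `accuracy`, `n_categories`,
#'   `rank_fungal_transitivity`, `rank_geo_variety`,
#'   `transitivity_outranks_geo`).
#' @export
sensitivity_splits <- function(features,
                               schemes = NULL,
                               seed, n_trees = 500) {
  yields <- attr(features, "yield")
  if (is.null(yields)) stop("features must carry the per-sample yields")
  if (is.null(schemes)) {
    # the density split is defined on block-level yields (yield is constant
    # within a block), not on the per-sample expansion
    blocks <- attr(features, "block_id")
    block_yields <- if (is.null(blocks)) yields else
      yields[!duplicated(blocks)]
    thr2 <- find_density_split(block_yields, 1)
    schemes <- list(two_way = thr2, three_way = c(26, 35),
                    four_way = c(20, 26, 35))
  }
  reports <- list(); comp <- list()
  for (nm in names(schemes)) {
    f <- features
    f$label <- categorize_yield(yields, schemes[[nm]])
    if (nlevels(droplevels(f$label)) < 2L)
      stop("scheme '", nm, "' puts all samples in one class")
    rep_ <- fit_probability_forest(f, seed = seed, n_trees = n_trees)
    reports[[nm]] <- rep_
    rk <- rank(-rep_$importance, ties.method = "min")
    rt <- unname(rk["fun_cooccurrence_transitivity"])
    rg <- unname(rk["geo_variety"])
    comp[[nm]] <- data.frame(
      scheme = nm, accuracy = rep_$accuracy,
      n_categories = nlevels(droplevels(f$label)),
      rank_fungal_transitivity = rt, rank_geo_variety = rg,
      transitivity_outranks_geo = isTRUE(rt < rg),
      stringsAsFactors = FALSE)
  }
  list(reports = reports, comparison = do.call(rbind, comp))
}

#' Block-level transitivity-yield regression
#'
#' Aggregates the fungal co-occurrence transitivity over each block's T0-T2
#' samples and regresses block yield on it by ordinary least squares. Yield
#' is constant within a block, so the block is the regression unit
#' (sample-level available via `level = "sample"`).
#'
#' @param props [properties_table()] output (metadata columns included).
#' @param meta validated metadata.
#' @param level `"block"` (default) or `"sample"`.
#' @return list with `slope`, `r_squared`, `p_value`, `n`, and the fitted
#'   `data` (aggregated predictor and yield).
#' @export
transitivity_yield_regression <- function(props, meta, level = c("block",
                                                                 "sample")) {
  level <- match.arg(level)
  m <- merge(meta, props[, c("sample_id", "fun_cooccurrence_transitivity")],
             by = "sample_id")
  m <- m[m$time_point %in% c("T0", "T1", "T2") & !is.na(m$yield_t_ha), ,
         drop = FALSE]
  if (level == "block") {
    agg <- stats::aggregate(
      cbind(transitivity = fun_cooccurrence_transitivity,
            yield = yield_t_ha) ~ block_id, data = m, FUN = mean)
  } else {
    agg <- data.frame(block_id = m$sample_id,
                      transitivity = m$fun_cooccurrence_transitivity,
                      yield = m$yield_t_ha)
  }
  if (nrow(agg) < 3) stop("need at least 3 blocks with yield")
  if (stats::sd(agg$transitivity) == 0)
    stop("zero-variance predictor: transitivity constant across blocks")
  fit <- stats::lm(yield ~ transitivity, data = agg)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = nrow(agg), data = agg)
}
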