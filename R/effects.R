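# Treatment x time interaction contrasts.
#
# The design follows the trial's logic: within one location and one time
# interval (e.g. T0 -> T1), the effect attributable to the treatment is the
# difference between the change over time in the treated arm and the change
# in the control arm. On CLR-transformed abundances that difference-of-changes
# is a log-ratio fold-change contrast; on local network properties it is the
# same contrast in property units. The contrast is the interaction
# coefficient of an ordinary least-squares fit of
# value ~ treatment + time + treatment:time on the two time points.

# OLS interaction fit for a response matrix (samples x targets).
fit_interaction_multi <- function(Y, treatment, time, t_from, t_to) {
  trt <- factor(treatment, levels = c("control", "treated"))
  tm <- factor(time, levels = c(t_from, t_to))
  q <- ncol(Y)
  bad <- data.frame(estimate = rep(NA_real_, q), se = NA_real_,
                    t = NA_real_, p = NA_real_, note = "untestable",
                    stringsAsFactors = FALSE)
  cells <- table(trt, tm)
  if (any(cells == 0)) return(bad)
  X <- stats::model.matrix(~ trt * tm)
  qrx <- qr(X)
  n <- nrow(X)
  if (qrx$rank < 4L || n - 4L < 1L) return(bad)
  coefs <- qr.coef(qrx, Y)
  res <- Y - X %*% coefs
  df <- n - 4L
  sigma2 <- colSums(res^2) / df
  xtx_kk <- chol2inv(qr.R(qrx))[4L, 4L]
  est <- coefs[4L, ]
  se <- sqrt(sigma2 * xtx_kk)
  tval <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(tval), df)
  note <- rep("", q)
  degen <- se <= .Machine$double.eps^0.5 * pmax(1, abs(est))
  if (any(degen)) {
    note[degen] <- "degenerate"
    p[degen] <- ifelse(abs(est[degen]) < 1e-12, 1, 0)
    tval[degen] <- ifelse(abs(est[degen]) < 1e-12, 0, Inf)
  }
  data.frame(estimate = est, se = se, t = tval, p = p, note = note,
             stringsAsFactors = FALSE)
}

#' Treatment-by-time interaction contrast
#'
#' @param values numeric vector named by sample id (e.g. one OTU's CLR
#'   abundances, or one local network property).
#' @param meta validated metadata.
#' @param location location to test (the analysis is per location).
#' @param interval length-2 character vector `c(t_from, t_to)`.
#' @param target label for the tested quantity.
#' @return one-row data.frame: `target`, `location`, `interval`, `estimate`
#'   (difference of changes, treated minus control), `se`, `t`, `p`, `note`
#'   (`"untestable"` when a design cell is empty, `"degenerate"` when the
#'   residual variance is zero).
#' @export
interaction_contrast <- function(values, meta, location, interval,
                                 target = "value") {
  stopifnot(length(interval) == 2L)
  sel <- meta$location == location & meta$time_point %in% interval
  m <- meta[sel, , drop = FALSE]
  v <- values[m$sample_id]
  if (anyNA(v)) stop("values missing for sample(s): ",
                     paste(utils::head(m$sample_id[is.na(v)], 5),
                           collapse = ", "))
  r <- fit_interaction_multi(matrix(v, ncol = 1), m$treatment, m$time_point,
                             interval[1L], interval[2L])
  data.frame(target = target, location = location,
             interval = paste(interval, collapse = "->"),
             r, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values on the original index (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Differential-abundance interaction scan
#'
#' Applies the interaction contrast to every OTU of a CLR matrix, separately
#' per location and time interval, and controls the FDR with
#' Benjamini-Hochberg within each (location, interval) family.
#'
#' @param clr [composition_matrix] in `clr` space (from zero-replaced counts).
#' @param meta validated metadata covering the CLR samples.
#' @param intervals list of `c(t_from, t_to)` pairs; defaults to T0->T1,
#'   T0->T2 and T0->T3.
#' @param locations locations to scan (default: all in `meta`).
#' @return data.frame with one row per OTU x location x interval:
#'   interaction estimate, `se`, `t`, `p`, `q`, `note`.
#' @export
differential_abundance_scan <- function(clr, meta,
                                        intervals = list(c("T0", "T1"),
                                                         c("T0", "T2"),
                                                         c("T0", "T3")),
                                        locations = NULL) {
  stopifnot(inherits(clr, "composition_matrix"), clr$space == "clr")
  if (is.null(locations)) locations <- sort(unique(meta$location))
  out <- list()
  for (loc in locations) {
    for (iv in intervals) {
      sel <- meta$location == loc & meta$time_point %in% iv
      m <- meta[sel, , drop = FALSE]
      ids <- intersect(m$sample_id, rownames(clr$values))
      m <- m[match(ids, m$sample_id), , drop = FALSE]
      Y <- clr$values[ids, , drop = FALSE]
      r <- fit_interaction_multi(Y, m$treatment, m$time_point, iv[1L], iv[2L])
      r$q <- if (all(is.na(r$p))) NA_real_ else bh_adjust(r$p)
      out[[length(out) + 1L]] <- data.frame(
        target = colnames(Y), location = loc,
        interval = paste(iv, collapse = "->"), r,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction scan over local network properties
#'
#' The same treatment x time contrast applied to each of the 12 local network
#' property columns of a [properties_table()] output, per location and
#' interval — the tabulation behind a "which structural property changed
#' under treatment, where and when" summary.
#'
#' @param props output of [properties_table()] (metadata columns included).
#' @param meta validated metadata.
#' @param intervals list of time intervals, as in
#'   [differential_abundance_scan()].
#' @return data.frame with `target` (property), `location`, `interval`,
#'   `estimate`, `se`, `t`, `p`, `direction` (+/-) and `note`.
#' @export
property_trajectory_scan <- function(props, meta,
                                     intervals = list(c("T0", "T1"),
                                                      c("T0", "T2"),
                                                      c("T0", "T3"))) {
  prop_cols <- grep("^(bac|fun)_(cooccurrence|coexclusion)_", names(props),
                    value = TRUE)
  if (!length(prop_cols)) stop("no property columns found")
  out <- list()
  for (loc in sort(unique(meta$location))) {
    for (iv in intervals) {
      sel <- meta$location == loc & meta$time_point %in% iv
      m <- meta[sel, , drop = FALSE]
      rows <- match(m$sample_id, props$sample_id)
      Y <- as.matrix(props[rows, prop_cols, drop = FALSE])
      r <- fit_interaction_multi(Y, m$treatment, m$time_point, iv[1L], iv[2L])
      out[[length(out) + 1L]] <- data.frame(
        target = prop_cols, location = loc,
        interval = paste(iv, collapse = "->"), r,
        direction = ifelse(is.na(r$estimate), "",
                           ifelse(r$estimate >= 0, "+", "-")),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
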