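#' Configuration of a synthetic field-trial study
#'
#' Defaults emulate the reference trial design: 3 locations, 10 treated and
#' 10 control blocks per location, four time points (T0/T3 bulk soil, T1/T2
#' rhizosphere), multinomial marker-gene counts at 8,000-60,000 reads per
#' sample, latent binary habitat factors driving planted co-occurrence and
#' co-exclusion blocks (presence probability 0.9 when the factor state
#' matches vs 0.2 baseline), treatment effects planted in only two of the
#' three locations, and a bimodal block-yield distribution (two low-yield
#' location intercepts, one high) linked to the transitivity of the
#' generating fungal co-occurrence network.
#'
#' @param n_locations number of locations.
#' @param blocks_per_arm blocks per treatment arm per location.
#' @param time_points time-point labels.
#' @param n_otus_bacteria,n_otus_fungi OTUs per marker domain.
#' @param depth_range sequencing depth range (reads/sample), ordered.
#' @param n_habitat_factors latent binary factors per marker.
#' @param planted_group_size OTUs per factor in the co-occurring block,
#'   named vector for bacteria/fungi.
#' @param anti_group_size OTUs per factor in the anti-coupled (co-excluding)
#'   block.
#' @param planted_pair_strength presence probability when the factor state
#'   favours the OTU.
#' @param baseline_presence presence probability otherwise.
#' @param n_planted_differential_otus differential OTUs planted per affected
#'   location (bacteria; fungi get half).
#' @param treatment_effect_log2fc planted interaction effect (log2 units).
#' @param yield_intercepts per-location yield intercepts (t/ha); recycled.
#' @param treatment_yield_effect yield gain (t/ha) from treatment in the
#'   affected locations.
#' @param yield_transitivity_slope slope of block yield on the block-mean
#'   generating fungal co-occurrence transitivity (centered at 0.2, the
#'   middle of the transitivity range the factor model produces).
#' @param yield_noise_sd Gaussian noise sd of block yield (t/ha).
#' @param rhizosphere_presence_factor multiplicative drop of background
#'   presence probability in rhizosphere samples (models the richness dip
#'   after planting).
#' @param activation_concentration multiplier on the Beta shape parameters of
#'   the block-level habitat-factor activation probabilities; values below 1
#'   widen the block-to-block spread of community structure (and hence of
#'   the transitivity that drives yield) without moving its mean.
#' @param seed RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_locations = 3,
                             blocks_per_arm = 10,
                             time_points = c("T0", "T1", "T2", "T3"),
                             n_otus_bacteria = 500,
                             n_otus_fungi = 200,
                             depth_range = c(8000, 60000),
                             n_habitat_factors = 6,
                             planted_group_size = c(bacteria = 10, fungi = 6),
                             anti_group_size = c(bacteria = 4, fungi = 3),
                             planted_pair_strength = 0.9,
                             baseline_presence = 0.2,
                             n_planted_differential_otus = 20,
                             treatment_effect_log2fc = 2,
                             yield_intercepts = c(23, 26, 38),
                             treatment_yield_effect = 3,
                             yield_transitivity_slope = 30,
                             yield_noise_sd = 1.5,
                             rhizosphere_presence_factor = 0.85,
                             activation_concentration = 1,
                             seed = 1) {
  cfg <- list(n_locations = n_locations, blocks_per_arm = blocks_per_arm,
              time_points = time_points, n_otus_bacteria = n_otus_bacteria,
              n_otus_fungi = n_otus_fungi, depth_range = depth_range,
              n_habitat_factors = n_habitat_factors,
              planted_group_size = planted_group_size,
              anti_group_size = anti_group_size,
              planted_pair_strength = planted_pair_strength,
              baseline_presence = baseline_presence,
              n_planted_differential_otus = n_planted_differential_otus,
              treatment_effect_log2fc = treatment_effect_log2fc,
              yield_intercepts = rep_len(yield_intercepts, n_locations),
              treatment_yield_effect = treatment_yield_effect,
              yield_transitivity_slope = yield_transitivity_slope,
              yield_noise_sd = yield_noise_sd,
              rhizosphere_presence_factor = rhizosphere_presence_factor,
              activation_concentration = activation_concentration,
              seed = seed)
  with(cfg, {
    stopifnot(n_locations >= 1, blocks_per_arm >= 1,
              n_otus_bacteria >= 1, n_otus_fungi >= 1,
              n_habitat_factors >= 1,
              length(depth_range) == 2, depth_range[1] > 0,
              depth_range[1] <= depth_range[2],
              planted_pair_strength > 0, planted_pair_strength < 1,
              baseline_presence > 0, baseline_presence < 1,
              rhizosphere_presence_factor > 0,
              rhizosphere_presence_factor <= 1,
              activation_concentration > 0,
              yield_noise_sd >= 0, n_planted_differential_otus >= 0,
              all(time_points %in% c("T0", "T1", "T2", "T3")))
    for (mk in c("bacteria", "fungi")) {
      n_otus <- if (mk == "bacteria") n_otus_bacteria else n_otus_fungi
      planted <- n_habitat_factors *
        (planted_group_size[[mk]] + anti_group_size[[mk]])
      if (planted > n_otus)
        stop("planted network blocks need ", planted, " ", mk,
             " OTUs but only ", n_otus, " configured")
    }
  })
  structure(cfg, class = "synthetic_config")
}

# per-location Beta parameters of habitat-factor activation probabilities:
# higher-yield locations have more active habitat factors, so their planted
# fungal subgraphs are denser and more transitive (the pathway that links
# community structure to yield).
activation_beta <- function(intercepts) {
  r <- rank(intercepts, ties.method = "first")
  r01 <- if (length(r) > 1) (r - 1) / (length(r) - 1) else 0.5
  list(shape1 = 1.2 + 1.6 * r01, shape2 = 2.8 - 1.6 * r01)
}

marker_otu_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

synth_taxonomy <- function(otu_ids, kingdom, n_genera = 40) {
  n <- length(otu_ids)
  g <- sample.int(n_genera, n, replace = TRUE,
                  prob = 1 / seq_len(n_genera))
  sprintf("%s;Phylum%02d;Class%02d;Order%02d;Family%02d;Genus%02d;",
          kingdom, (g - 1) %% 8 + 1, (g - 1) %% 12 + 1, (g - 1) %% 16 + 1,
          (g - 1) %% 24 + 1, g)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Presence/absence is generated first from the latent habitat-factor model
#' (so the incidence structure the pairwise co-occurrence test sees is
#' planted explicitly); abundances are then drawn conditionally on presence
#' from log-normal relative abundances with location, rhizosphere and
#' treatment effects, and counts multinomially at a random depth. Per-block
#' yield is a location intercept plus a slope on the block-mean transitivity
#' of the generating fungal co-occurrence network plus Gaussian noise.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_study`: `bacteria` and `fungi`
#'   ([otu_table]s), `metadata` (validated), `truth` (planted pairs,
#'   differential OTUs, yield parameters, per-block table), `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  locs <- paste0("Loc", seq_len(config$n_locations))
  high_loc <- locs[which.max(config$yield_intercepts)]
  affected <- utils::head(setdiff(locs, high_loc),
                          min(2, config$n_locations))
  if (!length(affected)) affected <- locs[1L]

  # ---- design ----
  blocks <- expand.grid(block = seq_len(2 * config$blocks_per_arm),
                        location = locs, stringsAsFactors = FALSE)
  blocks$treatment <- ifelse(blocks$block <= config$blocks_per_arm,
                             "control", "treated")
  blocks$block_id <- sprintf("%s_B%02d", blocks$location, blocks$block)
  meta <- merge(blocks,
                data.frame(time_point = config$time_points,
                           stringsAsFactors = FALSE))
  meta$soil_type <- ifelse(meta$time_point %in% c("T0", "T3"),
                           "bulk", "rhizosphere")
  meta$variety <- ifelse(meta$location == high_loc, "VarB", "VarA")
  meta$sample_id <- sprintf("%s_%s", meta$block_id, meta$time_point)
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  n_samp <- nrow(meta)

  ab <- activation_beta(config$yield_intercepts)
  truth_pairs_co <- list(); truth_pairs_cx <- list()
  truth_diff <- list(); tables <- list()
  fungal_planted_graph <- NULL

  for (mk in c("bacteria", "fungi")) {
    n_otus <- if (mk == "bacteria") config$n_otus_bacteria else
      config$n_otus_fungi
    prefix <- if (mk == "bacteria") "B" else "F"
    otus <- marker_otu_ids(prefix, n_otus)
    K <- config$n_habitat_factors
    gs <- config$planted_group_size[[mk]]
    as_ <- config$anti_group_size[[mk]]
    main_idx <- matrix(seq_len(K * gs), nrow = gs)          # col f = factor f
    anti_idx <- matrix(K * gs + seq_len(K * as_), nrow = as_)
    others <- setdiff(seq_len(n_otus), c(main_idx, anti_idx))

    # factor activation probability per block, activation per sample.
    # Only the fungal factors are location-graded (more active in
    # higher-yield locations): fungal community structure is the planted
    # yield pathway, bacterial structure is deliberately not.
    loc_i <- match(meta$location, locs)
    blk_i <- match(meta$block_id, blocks$block_id)
    if (mk == "fungi") {
      sh1 <- ab$shape1[match(blocks$location, locs)]
      sh2 <- ab$shape2[match(blocks$location, locs)]
    } else {
      sh1 <- rep(2, nrow(blocks)); sh2 <- rep(2, nrow(blocks))
    }
    sh1 <- sh1 * config$activation_concentration
    sh2 <- sh2 * config$activation_concentration
    # one habitat-quality level per block, shared by all factors of the
    # marker: block-level structure (hence transitivity, hence yield) varies
    # much more between blocks than the average of K independent factors
    # would, which is the mechanism the yield model is meant to recover
    quality <- stats::rbeta(nrow(blocks), sh1, sh2)
    p_act <- matrix(quality, nrow = nrow(blocks), ncol = K)
    active <- matrix(stats::rbinom(n_samp * K, 1, p_act[blk_i, ]) == 1,
                     nrow = n_samp, ncol = K)

    # presence probabilities
    pres_p <- matrix(0, n_samp, n_otus)
    for (f in seq_len(K)) {
      pres_p[, main_idx[, f]] <- ifelse(active[, f],
                                        config$planted_pair_strength,
                                        config$baseline_presence)
      pres_p[, anti_idx[, f]] <- ifelse(active[, f],
                                        config$baseline_presence,
                                        config$planted_pair_strength)
    }
    # background OTUs: per-OTU baseline prevalence with location- and
    # soil-specific logit shifts, so that location dominates beta-diversity
    # (incidence carries most of the CLR variance) and rhizosphere samples
    # are compositionally distinct from bulk soil
    q <- stats::rbeta(length(others), 1.2, 1.2)
    L_pres <- matrix(stats::rnorm(length(others) * length(locs), 0, 1.2),
                     length(others), length(locs))
    R_pres <- stats::rnorm(length(others), 0, 0.8)
    rhizo <- meta$soil_type == "rhizosphere"
    logit_q <- matrix(stats::qlogis(pmin(pmax(q, 1e-4), 1 - 1e-4)),
                      n_samp, length(others), byrow = TRUE) +
      t(L_pres)[loc_i, , drop = FALSE] + outer(rhizo, R_pres)
    rf <- ifelse(rhizo, config$rhizosphere_presence_factor, 1)
    pres_p[, others] <- stats::plogis(logit_q) * rf
    present <- matrix(stats::rbinom(length(pres_p), 1, pres_p),
                      n_samp, n_otus)
    empty <- rowSums(present) == 0
    if (any(empty)) present[empty, which.max(colMeans(pres_p))] <- 1L

    # planted pair truth (within-group co-occurrence, cross co-exclusion)
    pair_df <- function(idx_mat) {
      do.call(rbind, lapply(seq_len(ncol(idx_mat)), function(f) {
        ids <- otus[idx_mat[, f]]
        if (length(ids) < 2) return(NULL)
        cmb <- utils::combn(ids, 2)
        data.frame(marker = mk, factor = f, otu_a = cmb[1, ],
                   otu_b = cmb[2, ], stringsAsFactors = FALSE)
      }))
    }
    co <- rbind(pair_df(main_idx), pair_df(anti_idx))
    cx <- do.call(rbind, lapply(seq_len(K), function(f) {
      g <- expand.grid(otu_a = otus[main_idx[, f]],
                       otu_b = otus[anti_idx[, f]],
                       stringsAsFactors = FALSE)
      if (!nrow(g)) return(NULL)
      data.frame(marker = mk, factor = f, g, stringsAsFactors = FALSE)
    }))
    truth_pairs_co[[mk]] <- co
    truth_pairs_cx[[mk]] <- cx

    # abundances conditional on presence
    mu <- stats::rnorm(n_otus, 0, 1.2)
    L <- matrix(stats::rnorm(n_otus * length(locs), 0, 0.9),
                n_otus, length(locs))
    Rh <- stats::rnorm(n_otus, 0, 0.7)
    logab <- matrix(mu, n_samp, n_otus, byrow = TRUE) +
      t(L)[loc_i, , drop = FALSE] +
      outer(meta$soil_type == "rhizosphere", Rh)

    # planted treatment-by-time differential OTUs (affected locations only)
    n_pd <- if (mk == "bacteria") config$n_planted_differential_otus else
      ceiling(config$n_planted_differential_otus / 2)
    n_pd <- min(n_pd, length(others))
    if (n_pd > 0) {
      for (loc in affected) {
        diff_otus <- sample(others, n_pd)
        signs <- sample(c(-1, 1), n_pd, replace = TRUE)
        hit <- meta$location == loc & meta$treatment == "treated" &
          meta$time_point %in% c("T1", "T2")
        logab[hit, diff_otus] <- logab[hit, diff_otus] +
          matrix(signs * log(2) * config$treatment_effect_log2fc,
                 sum(hit), n_pd, byrow = TRUE)
        truth_diff[[paste(mk, loc)]] <- data.frame(
          marker = mk, otu = otus[diff_otus], location = loc,
          interval = "T0->T1,T0->T2", sign = signs,
          log2fc = config$treatment_effect_log2fc,
          stringsAsFactors = FALSE)
      }
    }
    logab <- logab + matrix(stats::rnorm(n_samp * n_otus, 0, 0.4),
                            n_samp, n_otus)
    lambda <- exp(logab) * present
    depth <- round(stats::runif(n_samp, config$depth_range[1],
                                config$depth_range[2]))
    counts <- matrix(0L, n_samp, n_otus,
                     dimnames = list(meta$sample_id, otus))
    for (i in seq_len(n_samp))
      counts[i, ] <- stats::rmultinom(1, depth[i], lambda[i, ])
    tables[[mk]] <- otu_table(
      counts, synth_taxonomy(otus, if (mk == "bacteria") "Bacteria" else
        "Fungi"), marker = if (mk == "bacteria") "16S" else "ITS")

    if (mk == "fungi") {
      # generating co-occurrence network: planted within-group cliques
      # embedded in a sparse unstructured background (mirrors the texture of
      # an estimated network: dense planted blocks plus scattered edges).
      # Without the background every induced subgraph of the disjoint
      # cliques would have transitivity exactly 1.
      bg <- which(upper.tri(matrix(0, n_otus, n_otus)), arr.ind = TRUE)
      keep_bg <- stats::runif(nrow(bg)) < 0.03
      edges <- rbind(co[, c("otu_a", "otu_b")],
                     data.frame(otu_a = otus[bg[keep_bg, 1L]],
                                otu_b = otus[bg[keep_bg, 2L]],
                                stringsAsFactors = FALSE))
      edges <- edges[!duplicated(edges), , drop = FALSE]
      fungal_planted_graph <- igraph::graph_from_data_frame(
        edges, directed = FALSE, vertices = data.frame(name = otus))
      fungal_present <- present
    }
  }

  # ---- yield from generating fungal co-occurrence transitivity ----
  f_otus <- marker_otu_ids("F", config$n_otus_fungi)
  yield_tp <- intersect(config$time_points, c("T0", "T1", "T2"))
  samp_trans <- rep(NA_real_, n_samp)
  for (i in which(meta$time_point %in% yield_tp)) {
    sub <- igraph::induced_subgraph(fungal_planted_graph,
                                    f_otus[fungal_present[i, ] > 0])
    tr <- igraph::transitivity(sub, type = "global")
    samp_trans[i] <- if (is.finite(tr)) tr else 0
  }
  blocks$mean_transitivity <- vapply(blocks$block_id, function(b) {
    mean(samp_trans[meta$block_id == b & meta$time_point %in% yield_tp])
  }, numeric(1))
  noise <- stats::rnorm(nrow(blocks), 0, config$yield_noise_sd)
  blocks$yield <- pmax(1, config$yield_intercepts[match(blocks$location,
                                                        locs)] +
    config$treatment_yield_effect *
      (blocks$location %in% affected & blocks$treatment == "treated") +
    config$yield_transitivity_slope * (blocks$mean_transitivity - 0.2) +
    noise)
  meta$yield_t_ha <- blocks$yield[match(meta$block_id, blocks$block_id)]

  meta_out <- meta[, c("sample_id", "location", "time_point", "treatment",
                       "block_id", "soil_type", "variety", "yield_t_ha")]
  rownames(meta_out) <- NULL
  truth <- list(
    planted_cooccurrence_pairs = do.call(rbind, truth_pairs_co),
    planted_coexclusion_pairs = do.call(rbind, truth_pairs_cx),
    planted_differential_otus = if (length(truth_diff))
      do.call(rbind, truth_diff) else NULL,
    yield_params = list(intercepts = stats::setNames(config$yield_intercepts,
                                                     locs),
                        slope = config$yield_transitivity_slope,
                        noise_sd = config$yield_noise_sd,
                        treatment_effect = config$treatment_yield_effect,
                        affected_locations = affected),
    blocks = blocks)
  rownames(truth$planted_cooccurrence_pairs) <- NULL
  rownames(truth$planted_coexclusion_pairs) <- NULL
  if (!is.null(truth$planted_differential_otus))
    rownames(truth$planted_differential_otus) <- NULL
  structure(list(bacteria = tables$bacteria, fungi = tables$fungi,
                 metadata = validate_metadata(meta_out), truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d samples, %d bacterial + %d fungal OTUs, %d blocks\n",
    nrow(x$metadata), n_otus(x$bacteria), n_otus(x$fungi),
    nrow(x$truth$blocks)))
  invisible(x)
}

fixture_configs <- function(seed) {
  list(
    tiny = synthetic_config(
      n_locations = 1, blocks_per_arm = 1, n_otus_bacteria = 12,
      n_otus_fungi = 8, depth_range = c(500, 2000), n_habitat_factors = 2,
      planted_group_size = c(bacteria = 3, fungi = 2),
      anti_group_size = c(bacteria = 1, fungi = 1),
      n_planted_differential_otus = 2, seed = seed),
    default = synthetic_config(seed = seed),
    `yield-linked` = synthetic_config(yield_transitivity_slope = 45,
                                      yield_noise_sd = 1.0,
                                      activation_concentration = 0.5,
                                      seed = seed))
}

#' Write a named study fixture to disk
#'
#' Generates one of the predefined study configurations (`"tiny"`: 8 samples
#' and 20 OTUs; `"default"`; `"yield-linked"`: stronger transitivity-yield
#' slope) and writes it through the package's TSV writers. Identical
#' `(name, seed)` produce byte-identical files.
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @param out_dir output directory (created if missing).
#' @return named character vector of written file paths.
#' @export
regenerate_fixture <- function(name = c("tiny", "default", "yield-linked"),
                               seed = 1, out_dir = tempdir()) {
  name <- match.arg(name)
  study <- generate_study(fixture_configs(seed)[[name]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bacteria = file.path(out_dir, paste0(name, "_16S.tsv")),
    fungi = file.path(out_dir, paste0(name, "_ITS.tsv")),
    metadata = file.path(out_dir, paste0(name, "_metadata.tsv")),
    truth = file.path(out_dir, paste0(name, "_truth.json")))
  write_otu_table(study$bacteria, paths[["bacteria"]])
  write_otu_table(study$fungi, paths[["fungi"]])
  write_metadata(study$metadata, paths[["metadata"]])
  tj <- jsonlite::toJSON(study$truth, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  writeLines(tj, paths[["truth"]], useBytes = TRUE)
  paths
}
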