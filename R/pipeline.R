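# Config-driven end-to-end orchestration:
# transform -> diversity -> networks -> local properties -> effects -> yield.
# Every stage writes plain-text outputs into the run directory; the manifest
# records md5 digests so reruns with an identical config are verifiably
# identical.

write_matrix_tsv <- function(m, path, what = "value") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con,
             useBytes = TRUE)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])),
                     collapse = "\t"), con, useBytes = TRUE)
  invisible(path)
}

write_df_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con,
               useBytes = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] to simulate the study, or `NULL`
#'   to read it from `paths`.
#' @param paths named list (`otu_16s`, `otu_its`, `metadata`) of input files,
#'   used when `synthetic` is `NULL`.
#' @param min_prevalence named prevalence thresholds per marker
#'   (defaults: 0.30 for 16S, 0.10 for ITS).
#' @param max_otus node cap for the networks (default 4000).
#' @param alpha per-tail significance level of the pair tests.
#' @param prior_strength zero-replacement prior mass (`NULL` = D/2 default).
#' @param permanova_terms ordered PERMANOVA terms.
#' @param n_perm PERMANOVA permutations.
#' @param n_components joint-projection components (default 70).
#' @param scheme yield thresholds (`NULL`: two-way at the density minimum).
#' @param seeds named list of seeds, one per stochastic stage:
#'   `simulate`, `permanova`, `yield`. All mandatory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       paths = NULL,
                       min_prevalence = c("16S" = 0.30, "ITS" = 0.10),
                       max_otus = 4000,
                       alpha = 0.05,
                       prior_strength = NULL,
                       permanova_terms = c("location", "time_point",
                                           "treatment"),
                       n_perm = 999,
                       n_components = 70,
                       scheme = NULL,
                       seeds = list(simulate = 1, permanova = 1, yield = 1)) {
  need <- c("simulate", "permanova", "yield")
  miss <- setdiff(need, names(seeds))
  if (length(miss) || any(vapply(seeds[need], is.null, logical(1))))
    stop("every stochastic stage needs an explicit seed; missing: ",
         paste(miss, collapse = ", "))
  if (any(min_prevalence <= 0 | min_prevalence >= 1))
    stop("prevalence thresholds must be in (0, 1)")
  if (is.null(synthetic) && is.null(paths))
    stop("either a synthetic config or input paths are required")
  structure(list(synthetic = synthetic, paths = paths,
                 min_prevalence = min_prevalence, max_otus = max_otus,
                 alpha = alpha, prior_strength = prior_strength,
                 permanova_terms = permanova_terms, n_perm = n_perm,
                 n_components = n_components, scheme = scheme,
                 seeds = seeds),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes transform -> diversity -> networks -> local properties ->
#' effects -> yield model on a synthetic or loaded study, writing each
#' stage's outputs as TSV/JSON under `out_dir` and returning a manifest with
#' per-file md5 digests. Rerunning with an identical config reproduces
#' identical digests.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return manifest list (also written to `manifest.json`): seeds, per-stage
#'   output digests and timings.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "rhizonet",
                   version = as.character(utils::packageVersion("rhizonet")),
                   seeds = config$seeds, stages = list())
  digest_files <- function(paths) {
    md5 <- tools::md5sum(unlist(paths))
    stats::setNames(unname(md5), basename(names(md5)))
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", outputs = as.list(digest_files(paths)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    paths
  }

  # ---- inputs ----
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- config$seeds$simulate
    study <- generate_study(cfg)
    tab16 <- study$bacteria; tabIT <- study$fungi; meta <- study$metadata
  } else {
    tab16 <- read_otu_table(config$paths$otu_16s, "16S")
    tabIT <- read_otu_table(config$paths$otu_its, "ITS")
    meta <- read_metadata(config$paths$metadata)
  }

  # ---- transform ----
  clr16 <- clrIT <- NULL
  run_stage("transform", function() {
    clr16 <<- clr_transform(replace_zeros(tab16,
                                          strength = config$prior_strength))
    clrIT <<- clr_transform(replace_zeros(tabIT,
                                          strength = config$prior_strength))
    p1 <- file.path(out_dir, "clr_16S.tsv")
    p2 <- file.path(out_dir, "clr_ITS.tsv")
    write_matrix_tsv(clr16$values, p1); write_matrix_tsv(clrIT$values, p2)
    c(p1, p2)
  })

  # ---- diversity ----
  d16 <- dIT <- NULL
  run_stage("diversity", function() {
    a16 <- alpha_diversity(tab16); aIT <- alpha_diversity(tabIT)
    names(a16)[-1] <- paste0("bac_", names(a16)[-1])
    names(aIT)[-1] <- paste0("fun_", names(aIT)[-1])
    alpha <- merge(a16, aIT, by = "sample_id")
    d16 <<- aitchison_distance(clr16); dIT <<- aitchison_distance(clrIT)
    pm16 <- permanova(d16, meta, config$permanova_terms,
                      n_perm = config$n_perm, seed = config$seeds$permanova)
    pmIT <- permanova(dIT, meta, config$permanova_terms,
                      n_perm = config$n_perm, seed = config$seeds$permanova)
    paths <- file.path(out_dir, c("alpha_diversity.tsv", "permanova_16S.tsv",
                                  "permanova_ITS.tsv"))
    write_df_tsv(alpha, paths[1])
    write_df_tsv(as.data.frame(pm16), paths[2])
    write_df_tsv(as.data.frame(pmIT), paths[3])
    paths
  })

  # ---- networks ----
  net16 <- netIT <- NULL
  run_stage("networks", function() {
    inc16 <- incidence_matrix(tab16); incIT <- incidence_matrix(tabIT)
    k16 <- filter_otus(inc16, config$min_prevalence[["16S"]],
                       max_otus = config$max_otus,
                       total_counts = colSums(tab16$counts))
    kIT <- filter_otus(incIT, config$min_prevalence[["ITS"]],
                       max_otus = config$max_otus,
                       total_counts = colSums(tabIT$counts))
    net16 <<- build_metacommunity(inc16, k16, alpha = config$alpha,
                                  marker = "16S", counts = tab16$counts,
                                  min_prevalence = config$min_prevalence[["16S"]],
                                  max_otus = config$max_otus)
    netIT <<- build_metacommunity(incIT, kIT, alpha = config$alpha,
                                  marker = "ITS", counts = tabIT$counts,
                                  min_prevalence = config$min_prevalence[["ITS"]],
                                  max_otus = config$max_otus)
    paths <- file.path(out_dir, c("network_16S.tsv", "network_ITS.tsv"))
    write_network(net16, paths[1]); write_network(netIT, paths[2])
    paths
  })

  # ---- local properties ----
  props <- NULL
  run_stage("local_properties", function() {
    props <<- properties_table(net16, netIT, tab16, tabIT, meta)
    p <- file.path(out_dir, "local_properties.tsv")
    write_df_tsv(props, p)
    p
  })

  # ---- effects ----
  run_stage("effects", function() {
    da16 <- differential_abundance_scan(clr16, meta)
    daIT <- differential_abundance_scan(clrIT, meta)
    pe <- property_trajectory_scan(props, meta)
    paths <- file.path(out_dir, c("differential_abundance_16S.tsv",
                                  "differential_abundance_ITS.tsv",
                                  "property_effects.tsv"))
    write_df_tsv(da16, paths[1]); write_df_tsv(daIT, paths[2])
    write_df_tsv(pe, paths[3])
    paths
  })

  # ---- yield model ----
  run_stage("yield_model", function() {
    ord <- joint_projection(clr16, clrIT, config$n_components)
    thr <- config$scheme
    if (is.null(thr)) {
      block_yields <- unique(meta[!is.na(meta$yield_t_ha),
                                  c("block_id", "yield_t_ha")])$yield_t_ha
      thr <- find_density_split(block_yields, 1)
    }
    feats <- assemble_features(ord, props, meta, thr)
    rep_ <- fit_probability_forest(feats, seed = config$seeds$yield)
    reg <- transitivity_yield_regression(props, meta)
    out <- list(thresholds = thr,
                n_train = rep_$n_train, n_test = rep_$n_test,
                accuracy = rep_$accuracy,
                confusion = as.data.frame(rep_$confusion),
                importance = as.list(round(rep_$importance, 10)),
                transitivity_yield = reg[c("slope", "r_squared", "p_value",
                                           "n")])
    p <- file.path(out_dir, "yield_report.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    p
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
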