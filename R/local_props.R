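# Per-sample ("local") network structure: the induced subgraph of the
# metacommunity network on the OTUs detected in one sample, summarized by
# modularity, transitivity and edge proportion for each edge type.

# igraph objects for the two edge types, built once per network
network_graphs <- function(network) {
  lapply(c(cooccurrence = "cooccurrence", coexclusion = "coexclusion"),
         function(ty) {
           e <- network$edges[network$edges$edge_type == ty, , drop = FALSE]
           igraph::graph_from_data_frame(
             e[, c("otu_a", "otu_b")], directed = FALSE,
             vertices = data.frame(name = network$nodes))
         })
}

graph_structure <- function(g) {
  m <- igraph::ecount(g)
  trans <- igraph::transitivity(g, type = "global")
  if (!is.finite(trans)) trans <- 0
  mod <- 0
  if (m > 0) {
    # greedy modularity maximization; agglomeration order is deterministic
    comm <- igraph::cluster_fast_greedy(g)
    mod <- igraph::modularity(comm)
  }
  list(n_edges = m, transitivity = trans, modularity = mod)
}

#' Local network properties of one sample
#'
#' @param network a [metacommunity_network].
#' @param sample_presence character vector of OTU ids detected in the sample
#'   (count > 0); only the intersection with the network nodes spans the
#'   local subgraph.
#' @param S total number of OTUs detected in the sample (all OTUs, not only
#'   network nodes); denominator of the edge proportions via `choose(S, 2)`.
#' @param sample_id label carried through to the output.
#' @return one-row data.frame with `sample_id`, `marker`, `S`, and for each of
#'   cooccurrence/coexclusion: `modularity`, `transitivity`, `proportion`.
#'   Transitivity is 0 when there is no connected triple, modularity 0 for an
#'   edgeless graph, proportion 0 when `S < 2`.
#' @export
local_properties <- function(network, sample_presence, S,
                             sample_id = NA_character_) {
  stopifnot(inherits(network, "metacommunity_network"))
  present <- intersect(sample_presence, network$nodes)
  if (S < length(present))
    stop("S cannot be smaller than the number of present network nodes")
  gs <- network_graphs(network)
  res <- lapply(gs, function(g) {
    graph_structure(igraph::induced_subgraph(g, present))
  })
  denom <- if (S >= 2) choose(S, 2) else Inf
  data.frame(
    sample_id = sample_id, marker = network$marker, S = as.integer(S),
    cooccurrence_modularity = res$cooccurrence$modularity,
    cooccurrence_transitivity = res$cooccurrence$transitivity,
    cooccurrence_proportion = res$cooccurrence$n_edges / denom,
    coexclusion_modularity = res$coexclusion$modularity,
    coexclusion_transitivity = res$coexclusion$transitivity,
    coexclusion_proportion = res$coexclusion$n_edges / denom,
    stringsAsFactors = FALSE)
}

# vectorized core: local properties for every sample of an incidence matrix
local_properties_all <- function(network, incidence) {
  gs <- network_graphs(network)
  node_idx <- colnames(incidence) %in% network$nodes
  S_all <- rowSums(incidence)
  out <- vector("list", nrow(incidence))
  for (i in seq_len(nrow(incidence))) {
    present <- colnames(incidence)[incidence[i, ] > 0 & node_idx]
    res <- lapply(gs, function(g)
      graph_structure(igraph::induced_subgraph(g, present)))
    S <- S_all[i]
    denom <- if (S >= 2) choose(S, 2) else Inf
    out[[i]] <- data.frame(
      sample_id = rownames(incidence)[i], marker = network$marker,
      S = as.integer(S),
      cooccurrence_modularity = res$cooccurrence$modularity,
      cooccurrence_transitivity = res$cooccurrence$transitivity,
      cooccurrence_proportion = res$cooccurrence$n_edges / denom,
      coexclusion_modularity = res$coexclusion$modularity,
      coexclusion_transitivity = res$coexclusion$transitivity,
      coexclusion_proportion = res$coexclusion$n_edges / denom,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Local property table for both marker domains
#'
#' Computes the six local properties per sample for each marker and joins them
#' wide (prefixes `bac_` and `fun_`) together with the metadata. Samples
#' missing from one marker's table get `NA` in that block (with a message).
#'
#' @param network_16s,network_its metacommunity networks of the two domains.
#' @param table_16s,table_its the corresponding [otu_table]s.
#' @param meta validated metadata.
#' @return data.frame, one row per metadata sample: metadata columns plus
#'   12 property columns and the two `S` counts.
#' @export
properties_table <- function(network_16s, network_its, table_16s, table_its,
                             meta) {
  p16 <- local_properties_all(network_16s, incidence_matrix(table_16s))
  pit <- local_properties_all(network_its, incidence_matrix(table_its))
  prop_cols <- setdiff(names(p16), c("sample_id", "marker"))
  names(p16)[match(prop_cols, names(p16))] <- paste0("bac_", prop_cols)
  names(pit)[match(prop_cols, names(pit))] <- paste0("fun_", prop_cols)
  out <- merge(meta, p16[, -match("marker", names(p16))],
               by = "sample_id", all.x = TRUE)
  out <- merge(out, pit[, -match("marker", names(pit))],
               by = "sample_id", all.x = TRUE)
  miss <- out$sample_id[!stats::complete.cases(
    out[, grep("^(bac|fun)_", names(out)), drop = FALSE])]
  if (length(miss))
    message("samples missing from a marker table: ",
            paste(utils::head(miss, 5), collapse = ", "))
  out[match(meta$sample_id, out$sample_id), , drop = FALSE]
}
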