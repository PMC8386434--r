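# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# quick otu_table from a plain matrix (samples x OTUs)
make_table <- function(m, taxonomy = NULL, marker = "16S") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("o%02d", seq_len(ncol(m)))
  otu_table(m, taxonomy, marker)
}

cached_study <- function(name = "default", seed = 1) {
  memo(paste0("study_", name, "_", seed),
       generate_study(rhizonet:::fixture_configs(seed)[[name]]))
}

# full derived analysis (CLR, networks, properties, ordination, features)
# for one study; used by the network/yield/acceptance tests
cached_analysis <- function(name = "yield-linked", seed = 1) {
  memo(paste0("analysis_", name, "_", seed), {
    st <- cached_study(name, seed)
    clr16 <- clr_transform(replace_zeros(st$bacteria))
    clrIT <- clr_transform(replace_zeros(st$fungi))
    inc16 <- incidence_matrix(st$bacteria)
    incIT <- incidence_matrix(st$fungi)
    net16 <- build_metacommunity(
      inc16, filter_otus(inc16, 0.30, total_counts = colSums(st$bacteria$counts)),
      marker = "16S", counts = st$bacteria$counts, min_prevalence = 0.30)
    netIT <- build_metacommunity(
      incIT, filter_otus(incIT, 0.10, total_counts = colSums(st$fungi$counts)),
      marker = "ITS", counts = st$fungi$counts, min_prevalence = 0.10)
    props <- properties_table(net16, netIT, st$bacteria, st$fungi,
                              st$metadata)
    ord <- joint_projection(clr16, clrIT, 70)
    thr <- find_density_split(st$truth$blocks$yield)
    feats <- assemble_features(ord, props, st$metadata, thr)
    list(study = st, clr16 = clr16, clrIT = clrIT, net16 = net16,
         netIT = netIT, props = props, ord = ord, thr = thr, feats = feats)
  })
}

# hand-built metacommunity network from an explicit edge list
toy_network <- function(nodes, edges_co = NULL, edges_cx = NULL,
                        marker = "ITS") {
  mk_edges <- function(e, type) {
    if (is.null(e) || !nrow(e)) return(NULL)
    data.frame(otu_a = e[, 1], otu_b = e[, 2], edge_type = type,
               p_lt = 0.5, p_gt = 0.01, observed_j = 5L, expected_j = 2.5,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(mk_edges(edges_co, "cooccurrence"),
                 mk_edges(edges_cx, "coexclusion"))
  if (is.null(edges)) edges <- rhizonet:::empty_edges()
  metacommunity_network(nodes, edges, marker = marker,
                        params = list(n_samples = 10L, min_prevalence = 0.1,
                                      max_otus = 4000L, alpha = 0.05))
}

# exhaustive-enumeration oracle for the pairwise co-occurrence tails:
# fix the first OTU's samples at 1..N1 (placements are exchangeable) and
# enumerate every placement of the second OTU
enum_pair_tails <- function(N, N1, N2, j) {
  if (N2 == 0 || N1 == 0) {
    js <- 0
  } else {
    s2 <- utils::combn(N, N2)
    js <- apply(s2, 2, function(s) sum(s <= N1))
  }
  c(p_lt = mean(js <= j), p_gt = mean(js >= j),
    p_eq = mean(js == j))
}
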