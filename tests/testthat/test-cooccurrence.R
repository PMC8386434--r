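test_that("incidence matrix is presence on raw counts", {
  tab <- make_table(matrix(c(0L, 3L, 5L, 0L), 2, byrow = TRUE))
  expect_equal(unname(incidence_matrix(tab)),
               matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE))
  allpos <- make_table(matrix(1:6, 2))
  expect_true(all(incidence_matrix(allpos) == 1))
  # column sums are per-OTU prevalence
  set.seed(1)
  tab2 <- make_table(matrix(rbinom(50, 1, 0.4) * rpois(50, 3), 10))
  expect_equal(unname(colSums(incidence_matrix(tab2))),
               unname(colSums(tab2$counts > 0)))
})

test_that("prevalence filter applies the 30% rule, caps and tie-breaks", {
  inc <- matrix(0L, 10, 4,
                dimnames = list(sprintf("s%d", 1:10),
                                c("keep3", "drop2", "keep9", "keep5")))
  inc[1:3, "keep3"] <- 1L; inc[1:2, "drop2"] <- 1L
  inc[1:9, "keep9"] <- 1L; inc[1:5, "keep5"] <- 1L
  kept <- filter_otus(inc, 0.30)
  expect_setequal(kept, c("keep3", "keep5", "keep9"))
  expect_equal(kept[1], "keep9")          # ordered by prevalence
  # cap on the number of OTUs
  expect_length(filter_otus(inc, 0.10, max_otus = 2), 2)
  # pair cap: choose(kept, 2) <= max_pairs
  inc2 <- matrix(1L, 10, 8, dimnames = list(NULL, letters[1:8]))
  expect_length(filter_otus(inc2, 0.5, max_pairs = 10), 5)
  # monotonicity: lower threshold keeps a superset
  expect_true(all(filter_otus(inc, 0.30) %in% filter_otus(inc, 0.10)))
  expect_error(filter_otus(inc, 0.999), "threshold")
  expect_error(filter_otus(inc, 0), "in \\(0, 1\\)")
})

test_that("pair-test tails match closed forms", {
  # N=4, N1=N2=2, j=2: P(X=2) = 1/6
  pt <- veech_pair_test(4, 2, 2, 2)
  expect_equal(pt$p_gt, 1 / 6, tolerance = 1e-12)
  expect_equal(pt$p_lt, 1, tolerance = 1e-12)
  expect_equal(pt$expected_j, 1)
  # ubiquitous OTU: degenerate support, both tails 1
  pt2 <- veech_pair_test(10, 10, 4, 4)
  expect_equal(pt2$p_lt, 1); expect_equal(pt2$p_gt, 1)
  # single-term extreme tail
  pt3 <- veech_pair_test(20, 10, 10, 10)
  expect_equal(pt3$p_gt, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(pt3$p_gt, 5.4125e-6, tolerance = 1e-4)
  # outside the support is an upstream bug
  expect_error(veech_pair_test(10, 6, 6, 1), "support")
  expect_error(veech_pair_test(10, 12, 2, 1), "N1")
})

test_that("tail identity p_lt + p_gt - P(X=j) = 1 on random pairs", {
  set.seed(6)
  for (i in 1:200) {
    N <- sample(5:150, 1)
    N1 <- sample(0:N, 1); N2 <- sample(0:N, 1)
    support <- seq(max(0, N1 + N2 - N), min(N1, N2))
    j <- support[sample.int(length(support), 1)]
    pt <- veech_pair_test(N, N1, N2, j)
    pj <- stats::dhyper(j, N1, N - N1, N2)
    expect_lt(abs(pt$p_lt + pt$p_gt - pj - 1), 1e-12)
  }
})

test_that("metacommunity classification uses tails plus direction", {
  inc <- matrix(0L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  inc[1:5, "a"] <- 1L; inc[1:5, "b"] <- 1L; inc[6:10, "c"] <- 1L
  net <- build_metacommunity(inc, c("a", "b", "c"), alpha = 0.05)
  e <- net$edges
  # identical incidence: p_gt = 1/C(10,5) ~ 0.00397 < 0.05 -> cooccurrence
  ab <- e[e$otu_a == "a" & e$otu_b == "b", ]
  expect_equal(ab$edge_type, "cooccurrence")
  expect_equal(ab$p_gt, 1 / choose(10, 5), tolerance = 1e-12)
  # mutually exclusive pair covering all samples -> coexclusion
  ac <- e[e$otu_a == "a" & e$otu_b == "c", ]
  expect_equal(ac$edge_type, "coexclusion")
  expect_equal(ac$p_lt, 1 / choose(10, 5), tolerance = 1e-12)
  # alpha = 0: no edges at all
  expect_equal(nrow(build_metacommunity(inc, c("a", "b", "c"),
                                        alpha = 0)$edges), 0L)
})

test_that("local properties on known graphs", {
  # triangle among 4 detected OTUs: transitivity 1, proportion 3/6
  net <- toy_network(c("a", "b", "c", "d"),
                     edges_co = data.frame(a = c("a", "b", "c"),
                                           b = c("b", "c", "a")))
  lp <- local_properties(net, c("a", "b", "c", "d"), S = 4, "s1")
  expect_equal(lp$cooccurrence_transitivity, 1)
  expect_equal(lp$cooccurrence_proportion, 0.5)
  expect_equal(lp$coexclusion_proportion, 0)
  # path a-b-c: no triangles
  path <- toy_network(c("a", "b", "c"),
                      edges_co = data.frame(a = c("a", "b"), b = c("b", "c")))
  expect_equal(local_properties(path, c("a", "b", "c"), 3)$
                 cooccurrence_transitivity, 0)
  # two disjoint triangles: greedy partition finds the components, Q = 0.5
  tri2 <- toy_network(letters[1:6],
                      edges_co = data.frame(
                        a = c("a", "b", "c", "d", "e", "f"),
                        b = c("b", "c", "a", "e", "f", "d")))
  lp2 <- local_properties(tri2, letters[1:6], 6)
  expect_equal(lp2$cooccurrence_modularity, 0.5, tolerance = 1e-10)
  # degenerate sample: everything zero
  lp3 <- local_properties(tri2, "a", 1)
  expect_equal(unlist(lp3[grep("_(modularity|transitivity|proportion)$",
                               names(lp3))], use.names = FALSE),
               rep(0, 6))
  expect_error(local_properties(tri2, letters[1:3], 2), "S cannot")
})

test_that("local edge sets are induced subgraphs of the metacommunity", {
  an <- cached_analysis()
  net <- an$netIT
  inc <- incidence_matrix(an$study$fungi)
  gs <- rhizonet:::network_graphs(net)
  meta_edges <- igraph::ecount(gs$cooccurrence)
  s <- rownames(inc)[1]
  present <- colnames(inc)[inc[s, ] > 0 & colnames(inc) %in% net$nodes]
  sub <- igraph::induced_subgraph(gs$cooccurrence, present)
  expect_lte(igraph::ecount(sub), meta_edges)
  # dropping one OTU never increases the local edge count
  e_full <- igraph::ecount(sub)
  for (drop in present[1:5]) {
    e_drop <- igraph::ecount(igraph::induced_subgraph(
      gs$cooccurrence, setdiff(present, drop)))
    expect_lte(e_drop, e_full)
  }
})

test_that("properties table joins both markers per sample", {
  an <- cached_analysis()
  props <- an$props
  expect_equal(nrow(props), nrow(an$study$metadata))
  expect_true(all(c("bac_cooccurrence_transitivity",
                    "fun_coexclusion_proportion") %in% names(props)))
  expect_true(all(props$bac_cooccurrence_proportion >= 0 &
                    props$bac_cooccurrence_proportion <= 1))
  expect_true(all(props$fun_cooccurrence_modularity >= -0.5 &
                    props$fun_cooccurrence_modularity <= 1))
  # a sample containing every network node reproduces the metacommunity graph
  net <- an$netIT
  lp <- local_properties(net, net$nodes, length(net$nodes))
  gs <- rhizonet:::network_graphs(net)
  full <- rhizonet:::graph_structure(gs$cooccurrence)
  expect_equal(lp$cooccurrence_transitivity, full$transitivity)
  expect_equal(lp$cooccurrence_modularity, full$modularity)
})
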