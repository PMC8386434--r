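# Edge-list serialization for metacommunity networks.
#
# Dialect: UTF-8 TSV with '#'-prefixed header lines carrying the node set and
# filter provenance, then a column header and one row per edge. Tail
# probabilities are printed with 12 significant decimals (%.12e) so the
# write -> read -> write cycle is byte-stable.

fmt_num <- function(x) sprintf("%.12e", x)

#' Write a metacommunity network as an edge-list TSV
#'
#' @param network a [metacommunity_network].
#' @param path output TSV path.
#' @param graphml optional path; when given, the co-occurrence and
#'   co-exclusion edge sets are additionally written as a single GraphML file
#'   with an `edge_type` attribute.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml = NULL) {
  stopifnot(inherits(network, "metacommunity_network"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  p <- network$params
  head_lines <- c(
    "# rhizonet network v1",
    paste0("# marker: ", network$marker),
    paste0("# nodes: ", paste(network$nodes, collapse = ",")),
    paste0("# n_samples: ", p$n_samples),
    paste0("# min_prevalence: ", fmt_num(p$min_prevalence)),
    paste0("# max_otus: ", p$max_otus),
    paste0("# alpha: ", fmt_num(p$alpha)),
    paste0("# abundance_fraction: ",
           ifelse(is.na(network$abundance_fraction), "NA",
                  fmt_num(network$abundance_fraction))))
  writeLines(head_lines, con, useBytes = TRUE)
  writeLines(paste(c("otu_a", "otu_b", "edge_type", "p_lt", "p_gt",
                     "observed_j", "expected_j"), collapse = "\t"),
             con, useBytes = TRUE)
  e <- network$edges
  if (nrow(e)) {
    lines <- paste(e$otu_a, e$otu_b, e$edge_type, fmt_num(e$p_lt),
                   fmt_num(e$p_gt),
                   format(e$observed_j, scientific = FALSE, trim = TRUE),
                   fmt_num(e$expected_j), sep = "\t")
    writeLines(lines, con, useBytes = TRUE)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      if (nrow(e)) e else data.frame(otu_a = character(), otu_b = character()),
      directed = FALSE,
      vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a metacommunity network written by [write_network()]
#'
#' @param path edge-list TSV path.
#' @return a [metacommunity_network].
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) stop("network file missing header field: ", key)
    sub(paste0("^# ", key, ": ?"), "", ln[1L])
  }
  nodes_raw <- get("nodes")
  nodes <- if (nzchar(nodes_raw))
    strsplit(nodes_raw, ",", fixed = TRUE)[[1L]] else character()
  num <- function(s) if (identical(s, "NA")) NA_real_ else as.numeric(s)
  int <- function(s) if (identical(s, "NA")) NA_integer_ else as.integer(s)
  ab <- get("abundance_fraction")
  edges <- if (length(body) > 1L) {
    f <- strsplit(body[-1L], "\t", fixed = TRUE)
    data.frame(
      otu_a = vapply(f, `[[`, "", 1L),
      otu_b = vapply(f, `[[`, "", 2L),
      edge_type = vapply(f, `[[`, "", 3L),
      p_lt = as.numeric(vapply(f, `[[`, "", 4L)),
      p_gt = as.numeric(vapply(f, `[[`, "", 5L)),
      observed_j = as.integer(vapply(f, `[[`, "", 6L)),
      expected_j = as.numeric(vapply(f, `[[`, "", 7L)),
      stringsAsFactors = FALSE)
  } else empty_edges()
  metacommunity_network(
    nodes = nodes, edges = edges, marker = get("marker"),
    params = list(n_samples = int(get("n_samples")),
                  min_prevalence = num(get("min_prevalence")),
                  max_otus = int(get("max_otus")),
                  alpha = num(get("alpha"))),
    abundance_fraction = num(ab))
}
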