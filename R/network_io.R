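#' Write a ceRNA network as node/edge tables and GraphML
#'
#' Produces three files sharing a path stem: `<prefix>_nodes.tsv` (columns
#' `id`, `kind` in lncRNA/miRNA/gene, plus the node statistics, `NA` where a
#' statistic does not apply to a node kind), `<prefix>_edges.tsv` (`from`,
#' `to`, `kind`) and `<prefix>.graphml` with identical topology for use in
#' Cytoscape-style viewers. An empty network yields valid header-only tables
#' plus the lone lncRNA node.
#'
#' @param network a `cerna_network` from [select_network()].
#' @param out_prefix path stem for the three output files.
#' @return character vector of the three paths written, invisibly.
#' @export
write_network <- function(network, out_prefix) {
  stopifnot(inherits(network, "cerna_network"))
  nodes <- network_node_table(network)
  paths <- paste0(out_prefix, c("_nodes.tsv", "_edges.tsv", ".graphml"))
  utils::write.table(nodes, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$edges, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, paths[3L], format = "graphml")
  invisible(paths)
}

network_node_table <- function(network) {
  m <- network$mirnas
  g <- network$genes
  data.frame(
    id = c(network$lnc_id, m$mirna_id, g$gene_id),
    kind = c("lncRNA", rep("miRNA", nrow(m)), rep("gene", nrow(g))),
    r = c(NA_real_, rep(NA_real_, nrow(m)), g$r),
    p = c(NA_real_, m$p, g$p),
    p_adj = c(NA_real_, m$p_adj, rep(NA_real_, nrow(g))),
    t = c(NA_real_, m$t, rep(NA_real_, nrow(g))),
    mean_abs_r_targets = c(NA_real_, m$mean_abs_r_targets,
                           rep(NA_real_, nrow(g))),
    stringsAsFactors = FALSE)
}

#' Read a network back from GraphML
#'
#' Round-trip companion of [write_network()]; mainly useful to verify that the
#' exported topology is intact.
#'
#' @param path a `.graphml` file written by [write_network()].
#' @return an [igraph::graph] object.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
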