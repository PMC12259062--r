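#' Build the signed regulatory network for one surface protein
#'
#' Turns a mediation classification table into a directed graph over four
#' node types: ICT genes, the protein's coding gene, the surface protein
#' `m`, and the phenotype `D`. The protein and the phenotype are always
#' connected (`m -> D`, weight `beta`). Each daICT gene contributes edges by
#' its mediation class: full mediation draws `t -> m` (weight `alpha_t`);
#' partial mediation draws both `t -> m` and `t -> D` (weight `delta_t`);
#' null mediation draws only `t -> D`; dropped genes are omitted. The coding
#' gene and its edge `g -> m` (weight `eta1`) enter only when its
#' transcription is significantly associated with protein abundance in the
#' trio model or the gene is differentially expressed. Edge signs follow
#' coefficient signs and are carried as colors (red positive, blue
#' negative). The rules admit no cycles, so the result is a DAG.
#'
#' @param protein surface protein name (the mediator node).
#' @param classification data.frame with columns `t`, `alpha`, `delta`,
#'   `class` (labels full/partial/null/dropped; the single-exposure label
#'   `"none"` is treated as `"null"` and `"not_daICT"` as `"dropped"`). An
#'   empty table yields the minimal network `m -> D`.
#' @param beta mediator-to-phenotype coefficient for the `m -> D` edge.
#' @param coding_gene_stats optional list with `gene`, `eta1` and
#'   `significant` (logical: trio-model significance or differential
#'   expression); the `g -> m` edge is added only when `significant`.
#' @param contrast label stored as a graph attribute.
#' @return An igraph directed graph with vertex attribute `type` and edge
#'   attributes `sign`, `weight`, `provenance`, `color`.
#' @examples
#' cls <- data.frame(t = c("RAB1A", "VAMP8"), alpha = c(0.3, -0.2),
#'                   delta = c(0, 0.1), class = c("full", "partial"))
#' net <- build_network("HLA-DR", cls, beta = -0.4)
#' igraph::E(net)
#' @export
build_network <- function(protein, classification, beta = NA_real_,
                          coding_gene_stats = NULL, contrast = NULL) {
  cls <- classification
  if (!is.null(cls) && nrow(cls)) {
    cls$class[cls$class == "none"] <- "null"
    cls$class[cls$class == "not_daICT"] <- "dropped"
    cls <- cls[cls$class != "dropped", , drop = FALSE]
  }
  edge <- function(from, to, w, prov) {
    data.frame(from = from, to = to,
               sign = ifelse(is.na(w) | w >= 0, "+", "-"),
               weight = w, provenance = prov)
  }
  edges <- edge(protein, "D", beta, "beta")
  if (!is.null(cls) && nrow(cls)) {
    to_m <- cls$class %in% c("full", "partial")
    to_d <- cls$class %in% c("partial", "null")
    if (any(to_m))
      edges <- rbind(edges, edge(cls$t[to_m], protein, cls$alpha[to_m], "alpha"))
    if (any(to_d))
      edges <- rbind(edges, edge(cls$t[to_d], "D", cls$delta[to_d], "delta"))
  }
  if (!is.null(coding_gene_stats) && isTRUE(coding_gene_stats$significant)) {
    edges <- rbind(edges, edge(coding_gene_stats$gene, protein,
                               coding_gene_stats$eta1 %||% NA_real_, "eta1"))
  }
  edges$color <- ifelse(edges$sign == "+", "red", "blue")
  nodes <- data.frame(name = unique(c(edges$from, edges$to)))
  cg <- if (is.null(coding_gene_stats)) character(0) else coding_gene_stats$gene
  nodes$type <- ifelse(nodes$name == protein, "protein",
                       ifelse(nodes$name == "D", "phenotype",
                              ifelse(nodes$name %in% cg, "coding_gene",
                                     "ict_gene")))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "protein", protein)
  if (!is.null(contrast)) g <- igraph::set_graph_attr(g, "contrast", contrast)
  g
}

#' Export a regulatory network
#'
#' Writes the graph as GraphML, DOT, or a TSV edge list
#' (`source`, `target`, `sign`, `weight`, `provenance`, `color`). GraphML
#' and the edge list round-trip losslessly through [read_network()]; the
#' color attribute encodes the sign (red positive, blue negative) for
#' downstream visualization.
#'
#' @param net an igraph network from [build_network()].
#' @param path output file.
#' @param format `"graphml"`, `"dot"` or `"edgelist"`.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- igraph::as_data_frame(net, what = "edges")
    names(df)[1:2] <- c("source", "target")
    write_tsv(df, path)
  } else {
    igraph::write_graph(net, path, format = format)
  }
  invisible(path)
}

#' Read a regulatory network back from disk
#'
#' @param path file written by [export_network()].
#' @param format `"graphml"` or `"edgelist"` (DOT is write-only).
#' @return An igraph graph.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- read_tsv(path)
    igraph::graph_from_data_frame(df, directed = TRUE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}
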