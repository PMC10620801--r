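#' Build a signed molecular ecological network
#'
#' Keeps edge (i, j) iff \code{|r_ij| >= cutoff} and \code{q_ij < qMax};
#' nodes left without any edge are dropped. Records the positive/negative
#' edge tally.
#'
#' @param fit a \linkS4class{SparccFit} with p/q computed (see
#'   \code{\link{sparccPvalues}}).
#' @param scan an \linkS4class{RmtScan} (or see \code{\link{pinCutoff}}).
#' @param qMax FDR threshold, default 0.05.
#' @param taxonomy optional named lineage vector for the nodes.
#' @return a \linkS4class{MicrobialNetwork}
#' @export
buildNetwork <- function(fit, scan, qMax = 0.05, taxonomy = NULL) {
    if (all(!is.finite(fit@q)))
        stop("fit has no q-values; run sparccPvalues() first")
    st <- scan@selected
    r <- fit@r
    ut <- upperPairs(nrow(r))
    keep <- abs(r[ut]) >= st & fit@q[ut] < qMax
    keep[is.na(keep)] <- FALSE
    if (!any(keep))
        stop("empty network: no pair passes |r| >= ", st, " and q < ",
             qMax)
    ids <- rownames(r) %||% paste0("V", seq_len(nrow(r)))
    pairs <- ut[keep, , drop = FALSE]
    edges <- data.frame(
        source = ids[pairs[, 1]],
        target = ids[pairs[, 2]],
        r = r[pairs],
        p = fit@p[pairs],
        q = fit@q[pairs],
        sign = ifelse(r[pairs] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$source, edges$target)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    if (!is.null(taxonomy))
        igraph::V(g)$taxonomy <- unname(taxonomy[nodes])
    new("MicrobialNetwork", graph = g, edges = edges, cutoff = st,
        qMax = qMax)
}

#' Construct a network directly from a graph
#'
#' Wraps an existing \pkg{igraph} graph (or edge list) as a
#' \linkS4class{MicrobialNetwork}, for topology analysis of graphs that did
#' not come from a SparCC fit (null models, literature networks, toys).
#' Edge weights default to +1 with q = 0.
#'
#' @param g an undirected simple \pkg{igraph} graph.
#' @param r optional edge correlation vector aligned with
#'   \code{igraph::E(g)}.
#' @return a \linkS4class{MicrobialNetwork}
#' @export
asNetwork <- function(g, r = NULL) {
    if (!igraph::is_igraph(g)) stop("g must be an igraph graph")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g)
    g <- igraph::simplify(g)
    if (is.null(igraph::V(g)$name))
        igraph::V(g)$name <- paste0("V", seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g)
    if (is.null(r)) r <- rep(1, nrow(el))
    edges <- data.frame(source = el[, 1], target = el[, 2], r = r,
                        p = 0, q = 0,
                        sign = ifelse(r > 0, "positive", "negative"),
                        stringsAsFactors = FALSE)
    new("MicrobialNetwork", graph = g, edges = edges, cutoff = 0,
        qMax = 1)
}

#' Positive/negative edge tally
#'
#' @param net a \linkS4class{MicrobialNetwork}
#' @return named vector: positive, negative counts and
#'   \code{positivePct} (percent of edges positive).
#' @export
edgeSignSummary <- function(net) {
    pos <- sum(net@edges$sign == "positive")
    neg <- sum(net@edges$sign == "negative")
    c(positive = pos, negative = neg,
      positivePct = 100 * pos / max(pos + neg, 1))
}

#' Export a network as GraphML and node/edge TSVs
#'
#' @param net a \linkS4class{MicrobialNetwork}
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return invisibly, the paths written
#' @export
writeNetwork <- function(net, dir, prefix = "network") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gml <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(net@graph, gml, format = "graphml")
    edgeTsv <- file.path(dir, paste0(prefix, "_edges.tsv"))
    utils::write.table(net@edges, edgeTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tax <- igraph::vertex_attr(net@graph, "taxonomy")
    nodesDf <- data.frame(node = igraph::V(net@graph)$name,
                          degree = igraph::degree(net@graph),
                          taxonomy = if (is.null(tax)) NA else tax)
    nodeTsv <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    utils::write.table(nodesDf, nodeTsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(gml, edgeTsv, nodeTsv))
}
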