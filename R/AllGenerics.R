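#' Accessors for microMEN classes
#'
#' \code{otuCounts} returns the counts matrix (taxa x samples);
#' \code{taxonomy} the lineage strings; \code{sampleGroups} the per-sample
#' group labels (or NULL); \code{metalConcentrations} the per-sample metal
#' matrix (or NULL); \code{correlations} the SparCC r matrix;
#' \code{membership} the node -> module map; \code{eigengenes} the
#' samples x modules eigengene matrix.
#'
#' @param x a microMEN object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("metalConcentrations",
           function(x) standardGeneric("metalConcentrations"))

#' @rdname accessors
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setMethod("otuCounts", "OtuExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("taxonomy", "OtuExperiment", function(x) {
    tx <- SummarizedExperiment::rowData(x)$taxonomy
    names(tx) <- rownames(x)
    tx
})

#' @rdname accessors
#' @export
setMethod("sampleGroups", "OtuExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"group" %in% colnames(cd)) return(NULL)
    g <- cd$group
    names(g) <- rownames(cd)
    g
})

#' @rdname accessors
#' @export
setMethod("metalConcentrations", "OtuExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    keep <- setdiff(colnames(cd), "group")
    if (!length(keep)) return(NULL)
    as.matrix(as.data.frame(cd[, keep, drop = FALSE]))
})

#' @rdname accessors
#' @export
setMethod("correlations", "SparccFit", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("membership", "ModulePartition", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("eigengenes", "EigengeneResult", function(x) x@eigengenes)

#' @describeIn accessors number of edges kept in a network
#' @export
setMethod("length", "MicrobialNetwork", function(x)
    igraph::ecount(x@graph))

setMethod("show", "OtuExperiment", function(object) {
    cat("OtuExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
    g <- sampleGroups(object)
    if (!is.null(g)) {
        tb <- table(g)
        cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "),
            "\n")
    }
    m <- metalConcentrations(object)
    if (!is.null(m))
        cat("  metals:", paste(colnames(m), collapse = ", "), "\n")
    cat("  depth range:",
        paste(range(colSums(otuCounts(object))), collapse = "-"), "\n")
})

setMethod("show", "PlantedModel", function(object) {
    mods <- table(object@moduleAssignment[object@moduleAssignment > 0])
    cat("PlantedModel:", length(object@taxonIds), "taxa,",
        length(mods), "planted modules,",
        nrow(object@edgeTruth), "planted edges\n")
    cat("  samples per group:",
        paste(names(object@nSamplesPerGroup), object@nSamplesPerGroup,
              sep = "=", collapse = ", "), "\n")
    if (nrow(object@metalLoadings))
        cat("  metal loadings:",
            paste(object@metalLoadings$metal, "-> module",
                  object@metalLoadings$module, collapse = "; "), "\n")
})

setMethod("show", "SparccFit", function(object) {
    cat("SparccFit:", nrow(object@r), "taxa,",
        object@nResamples, "Dirichlet resamples\n")
    if (object@nPermutations > 0)
        cat("  significance from", object@nPermutations, "permutations\n")
    else cat("  p-values not yet computed\n")
})

setMethod("show", "RmtScan", function(object) {
    cat("RmtScan over", length(object@grid), "cut-offs [",
        min(object@grid), ",", max(object@grid), "]; selected s_t =",
        object@selected, "\n")
})

setMethod("show", "MicrobialNetwork", function(object) {
    g <- object@graph
    sgn <- table(factor(object@edges$sign, levels = c("positive",
                                                      "negative")))
    cat("MicrobialNetwork:", igraph::vcount(g), "nodes,",
        igraph::ecount(g), "edges (", sgn[["positive"]], "positive /",
        sgn[["negative"]], "negative )\n")
    cat("  |r| >=", object@cutoff, ", q <", object@qMax, "\n")
})

setMethod("show", "ModulePartition", function(object) {
    cat("ModulePartition:", length(object@sizes), "modules, Q =",
        round(object@modularity, 4), ";",
        sum(object@sizes > 4), "modules with >4 nodes\n")
})

setMethod("show", "EigengeneResult", function(object) {
    cat("EigengeneResult:", ncol(object@eigengenes), "module eigengenes over",
        nrow(object@eigengenes), "samples\n")
    cat("  variance explained:",
        paste(round(object@varianceExplained, 2), collapse = ", "), "\n")
})
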