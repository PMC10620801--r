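#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' OtuExperiment: an OTU count table with taxonomy and sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment}: the single \code{"counts"}
#' assay holds a non-negative integer taxa x samples matrix, \code{rowData}
#' carries a seven-rank semicolon-delimited \code{taxonomy} lineage per OTU,
#' and \code{colData} optionally carries a \code{group} label
#' (\code{"exposure"}/\code{"control"}) plus one column per measured metal
#' (concentrations in ug/L).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cnt)))
            msg <- c(msg, "counts must be finite")
        else if (any(cnt < 0))
            msg <- c(msg, "counts must be non-negative")
        else if (any(cnt != round(cnt)))
            msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate taxon ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (!"taxonomy" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData column 'taxonomy' is required")
    if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
        g <- SummarizedExperiment::colData(object)$group
        if (!all(g %in% c("exposure", "control")))
            msg <- c(msg, "group labels must be 'exposure' or 'control'")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an OtuExperiment
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in
#'   columns; must have row and column names.
#' @param taxonomy character vector of lineage strings
#'   (\code{"k__...;p__...;...;s__..."}), one per taxon. Defaults to
#'   unclassified lineages.
#' @param group optional per-sample label, \code{"exposure"} or
#'   \code{"control"}.
#' @param metals optional data.frame/matrix of per-sample metal
#'   concentrations (ug/L), rows matching samples.
#' @return an \linkS4class{OtuExperiment}
#' @examples
#' cnt <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
#' oe <- OtuExperiment(cnt)
#' @export
OtuExperiment <- function(counts, taxonomy = NULL, group = NULL,
                          metals = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("S", seq_len(ncol(counts)))
    storage.mode(counts) <- "double"
    if (is.null(taxonomy))
        taxonomy <- rep(emptyLineage(), nrow(counts))
    if (length(taxonomy) != nrow(counts))
        stop("taxonomy length (", length(taxonomy),
             ") does not match taxon count (", nrow(counts), ")")
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(group)) {
        group <- as.character(group)
        if (length(group) != ncol(counts))
            stop("group length does not match sample count")
        cd$group <- group
    }
    if (!is.null(metals)) {
        metals <- as.data.frame(metals)
        if (nrow(metals) != ncol(counts))
            stop("metals rows do not match sample count")
        if (any(metals < 0, na.rm = TRUE))
            stop("metal concentrations must be non-negative")
        for (m in colnames(metals)) cd[[m]] <- metals[[m]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(taxonomy = as.character(taxonomy),
                                       row.names = rownames(counts)),
        colData = cd)
    new("OtuExperiment", se)
}

#' Planted ground-truth model for synthetic OTU tables
#'
#' Encodes the generating process of a synthetic study: a block-structured
#' basis correlation matrix on the log-abundance scale (blocks = planted
#' modules), per-taxon log means/sds, group log-fold-changes, and linear
#' metal-module couplings.
#'
#' @slot taxonIds character, taxon names.
#' @slot moduleAssignment integer, planted module id per taxon (0 =
#'   background, not in any module).
#' @slot basisCorrelation taxa x taxa positive-semidefinite correlation
#'   matrix of log basis abundances.
#' @slot logMean,logSd per-taxon log-scale mean and sd of basis abundance.
#' @slot edgeTruth data.frame (i, j, rho): planted associations and their
#'   correlation after any PSD repair.
#' @slot groupEffects per-taxon natural-log fold change (exposure minus
#'   control).
#' @slot metalLoadings data.frame (metal, module, coefficient, noiseSd).
#' @slot nSamplesPerGroup named integer, c(exposure=, control=).
#' @slot seed integer master seed.
#' @exportClass PlantedModel
setClass("PlantedModel", representation(
    taxonIds = "character",
    moduleAssignment = "integer",
    basisCorrelation = "matrix",
    logMean = "numeric",
    logSd = "numeric",
    edgeTruth = "data.frame",
    groupEffects = "numeric",
    metalLoadings = "data.frame",
    nSamplesPerGroup = "integer",
    seed = "integer"))

setValidity("PlantedModel", function(object) {
    msg <- NULL
    p <- length(object@taxonIds)
    C <- object@basisCorrelation
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
        msg <- c(msg, "basisCorrelation must be symmetric")
    else if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <
             -1e-6)
        msg <- c(msg, "basisCorrelation must be positive semidefinite")
    if (length(object@moduleAssignment) != p ||
        length(object@logMean) != p || length(object@logSd) != p ||
        length(object@groupEffects) != p)
        msg <- c(msg, "per-taxon slots must match taxon count")
    if (any(!is.finite(object@groupEffects)))
        msg <- c(msg, "group effects must be finite")
    if (nrow(object@edgeTruth) > 0) {
        m <- object@moduleAssignment
        same <- m[object@edgeTruth$i] == m[object@edgeTruth$j] &
            m[object@edgeTruth$i] > 0
        if (!all(same))
            msg <- c(msg, "planted edges must join taxa of the same module")
    }
    if (is.null(msg)) TRUE else msg
})

#' SparCC correlation estimate with significance
#'
#' @slot r taxa x taxa basis correlation matrix, unit diagonal, in [-1, 1].
#' @slot p,q raw and BH-adjusted two-sided permutation p-values (NA until
#'   \code{\link{sparccPvalues}} is run).
#' @slot nResamples number of Dirichlet resamples aggregated by the median.
#' @slot nPermutations permutations behind p (0 before testing).
#' @exportClass SparccFit
setClass("SparccFit", representation(
    r = "matrix", p = "matrix", q = "matrix",
    nResamples = "integer", nPermutations = "integer"))

setValidity("SparccFit", function(object) {
    msg <- NULL
    r <- object@r
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
        msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8)
        msg <- c(msg, "r must have unit diagonal")
    if (any(abs(r) > 1 + 1e-8))
        msg <- c(msg, "r must lie in [-1, 1]")
    pv <- object@p[is.finite(object@p)]
    if (length(pv) && (min(pv) < 0 || max(pv) > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Random-matrix-theory cut-off scan
#'
#' For each candidate cut-off, the chi-square distances of the unfolded
#' eigenvalue nearest-neighbour spacing distribution (NNSD) to the Poisson
#' and Wigner-Dyson laws. The selected cut-off is the smallest grid point
#' where the NNSD is closer to Poisson.
#'
#' @slot grid strictly increasing candidate cut-offs in (0, 1).
#' @slot chiPoisson,chiWigner per-cut-off chi-square distances (NA where the
#'   thresholded spectrum was too degenerate to unfold).
#' @slot nEigen number of non-degenerate eigenvalues per cut-off.
#' @slot selected the chosen cut-off.
#' @exportClass RmtScan
setClass("RmtScan", representation(
    grid = "numeric", chiPoisson = "numeric", chiWigner = "numeric",
    nEigen = "integer", selected = "numeric"))

setValidity("RmtScan", function(object) {
    msg <- NULL
    if (any(diff(object@grid) <= 0))
        msg <- c(msg, "grid must be strictly increasing")
    if (length(object@selected) == 1 && is.finite(object@selected) &&
        !any(abs(object@grid - object@selected) < 1e-12))
        msg <- c(msg, "selected cut-off must lie on the grid")
    if (is.null(msg)) TRUE else msg
})

#' Signed molecular ecological network
#'
#' Undirected simple graph over OTU nodes; every edge passed both the
#' correlation cut-off and the FDR filter and carries the SparCC r, raw p,
#' adjusted q and sign.
#'
#' @slot graph an \pkg{igraph} undirected simple graph; vertex attribute
#'   \code{taxonomy}.
#' @slot edges data.frame (source, target, r, p, q, sign).
#' @slot cutoff correlation cut-off used.
#' @slot qMax FDR threshold used.
#' @exportClass MicrobialNetwork
setClass("MicrobialNetwork", representation(
    graph = "ANY", edges = "data.frame", cutoff = "numeric",
    qMax = "numeric"))

setValidity("MicrobialNetwork", function(object) {
    msg <- NULL
    g <- object@graph
    if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
    else {
        if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
        if (igraph::any_loop(g)) msg <- c(msg, "graph must have no loops")
        if (igraph::any_multiple(g))
            msg <- c(msg, "graph must have no duplicate edges")
        if (nrow(object@edges) != igraph::ecount(g))
            msg <- c(msg, "edge table does not match graph")
    }
    if (nrow(object@edges) > 0 &&
        any(abs(object@edges$r) < object@cutoff - 1e-12))
        msg <- c(msg, "all edges must satisfy |r| >= cutoff")
    if (is.null(msg)) TRUE else msg
})

#' Module partition of a network
#'
#' @slot membership named integer, module id (1-based, ordered by first
#'   appearance of each module's smallest node) per node.
#' @slot modularity Newman-Girvan Q of the partition on the unweighted graph.
#' @slot sizes integer module sizes.
#' @exportClass ModulePartition
setClass("ModulePartition", representation(
    membership = "integer", modularity = "numeric", sizes = "integer"))

setValidity("ModulePartition", function(object) {
    msg <- NULL
    if (is.null(names(object@membership)))
        msg <- c(msg, "membership must be named by node")
    if (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9)
        msg <- c(msg, "Q must lie in [-0.5, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Module eigengene analysis result
#'
#' @slot eigengenes samples x modules matrix; each column is the first
#'   principal axis of the module's standardized member-abundance submatrix,
#'   scaled to unit variance and signed to correlate positively with the
#'   module's mean standardized member profile.
#' @slot varianceExplained fraction of member variance captured per module.
#' @slot moduleCor Pearson correlation matrix between eigengenes.
#' @slot clustering hclust of modules on 1 - eigengene correlation
#'   (supergroup display), or NULL when fewer than 3 modules.
#' @exportClass EigengeneResult
setClass("EigengeneResult", representation(
    eigengenes = "matrix", varianceExplained = "numeric",
    moduleCor = "matrix", clustering = "ANY"))

setValidity("EigengeneResult", function(object) {
    msg <- NULL
    v <- apply(object@eigengenes, 2, stats::var)
    if (length(v) && max(abs(v - 1)) > 1e-6)
        msg <- c(msg, "eigengenes must have unit variance")
    ve <- object@varianceExplained
    if (length(ve) && (min(ve) <= 0 || max(ve) > 1 + 1e-9))
        msg <- c(msg, "variance explained must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})
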