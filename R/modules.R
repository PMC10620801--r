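#' Greedy (CNM) modularity optimization
#'
#' Agglomerative Clauset-Newman-Moore community detection on the
#' unweighted graph: start from singleton modules and repeatedly merge the
#' pair of connected modules with the largest modularity gain
#' \eqn{\Delta Q = 2 (e_{ij} - a_i a_j)} until no merge increases Q.
#' Ties are broken deterministically by the smallest (module id, module id)
#' pair, module ids being the smallest original node index in each module.
#' An edgeless graph yields all singletons with Q = 0.
#'
#' @param net a \linkS4class{MicrobialNetwork} or igraph graph.
#' @return a \linkS4class{ModulePartition}
#' @references Clauset, Newman & Moore (2004) Phys Rev E 70:066111.
#' @export
greedyModularity <- function(net) {
    g <- if (is(net, "MicrobialNetwork")) net@graph else net
    n <- igraph::vcount(g)
    if (n < 1) stop("empty graph")
    nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
    m <- igraph::ecount(g)
    if (m == 0) {
        memb <- stats::setNames(seq_len(n), nodes)
        return(new("ModulePartition", membership = memb, modularity = 0,
                   sizes = rep(1L, n)))
    }
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    e <- A / (2 * m)                 # module-aggregated edge fractions
    a <- rowSums(e) + diag(e)        # degree fractions (diag of e is 0)
    diag(e) <- 0
    label <- seq_len(n)              # module id = smallest member index
    active <- rep(TRUE, n)
    repeat {
        dq <- 2 * (e - outer(a, a))
        dq[e == 0] <- -Inf           # only connected modules can gain
        dq[!active, ] <- -Inf
        dq[, !active] <- -Inf
        diag(dq) <- -Inf
        mx <- max(dq)
        if (mx <= 1e-14) break
        hits <- which(dq >= mx - 1e-14, arr.ind = TRUE)
        hits <- hits[hits[, 1] != hits[, 2], , drop = FALSE]
        key <- cbind(pmin(label[hits[, 1]], label[hits[, 2]]),
                     pmax(label[hits[, 1]], label[hits[, 2]]))
        pick <- order(key[, 1], key[, 2])[1]
        i <- hits[pick, 1]; j <- hits[pick, 2]
        if (label[j] < label[i]) { tmp <- i; i <- j; j <- tmp }
        ## merge j into i
        e[i, ] <- e[i, ] + e[j, ]
        e[, i] <- e[, i] + e[, j]
        e[i, i] <- 0    # within-module mass not tracked; Q recomputed below
        a[i] <- a[i] + a[j]
        e[j, ] <- 0; e[, j] <- 0
        active[j] <- FALSE
        label[label == label[j]] <- label[i]
    }
    ## Q of the final partition, recomputed from the graph for exactness
    memb0 <- match(label, sort(unique(label)))
    Q <- igraph::modularity(g, memb0)
    ## relabel module ids by first appearance of the smallest member
    ord <- order(vapply(split(seq_len(n), memb0), min, numeric(1)))
    remap <- match(seq_along(ord), ord)
    memb <- stats::setNames(remap[memb0], nodes)
    sizes <- as.integer(table(memb))
    new("ModulePartition", membership = memb, modularity = Q,
        sizes = sizes)
}

#' @describeIn greedyModularity number of modules with more than
#'   \code{minSize} nodes (the paper-style "modules with >4 nodes" count
#'   uses the default).
#' @param partition a \linkS4class{ModulePartition}
#' @param minSize size strictly exceeded, default 4.
#' @export
modulesLargerThan <- function(partition, minSize = 4) {
    sum(partition@sizes > minSize)
}

#' Zi-Pi topological roles
#'
#' Within-module degree z-score
#' \eqn{Z_i = (k_{i,own} - \bar k_{own}) / sd(k_{own})} (0 when the module
#' sd is 0) and among-module connectivity
#' \eqn{P_i = 1 - \sum_m (k_{i,m}/k_i)^2}. Roles: network hub
#' (Zi > 2.5 and Pi > 0.62), module hub (Zi > 2.5), connector
#' (Pi > 0.62), otherwise peripheral. Module hubs and connectors are the
#' keystone taxa.
#'
#' @param net a \linkS4class{MicrobialNetwork}
#' @param partition a \linkS4class{ModulePartition} covering all nodes.
#' @return data.frame (node, module, Zi, Pi, role, isolated)
#' @export
ziPi <- function(net, partition) {
    g <- if (is(net, "MicrobialNetwork")) net@graph else net
    nodes <- igraph::V(g)$name
    memb <- membership(partition)
    if (!all(nodes %in% names(memb)))
        stop("partition does not cover all nodes")
    memb <- memb[nodes]
    n <- length(nodes)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    mods <- sort(unique(memb))
    ## k_im: links from node i into module m
    kim <- vapply(mods, function(m) rowSums(A[, memb == m, drop = FALSE]),
                  numeric(n))
    if (is.null(dim(kim))) kim <- matrix(kim, nrow = n)
    k <- rowSums(kim)
    own <- match(memb, mods)
    kOwn <- kim[cbind(seq_len(n), own)]
    Zi <- numeric(n)
    for (m in seq_along(mods)) {
        inM <- own == m
        mu <- mean(kOwn[inM])
        sdv <- stats::sd(kOwn[inM])
        Zi[inM] <- if (is.na(sdv) || sdv == 0) 0 else
            (kOwn[inM] - mu) / sdv
    }
    isolated <- k == 0
    Pi <- ifelse(isolated, 0, 1 - rowSums((kim / pmax(k, 1))^2))
    role <- rep("peripheral", n)
    role[Zi > 2.5] <- "module hub"
    role[Zi <= 2.5 & Pi > 0.62] <- "connector"
    role[Zi > 2.5 & Pi > 0.62] <- "network hub"
    data.frame(node = nodes, module = unname(memb), Zi = Zi, Pi = Pi,
               role = role, isolated = isolated,
               stringsAsFactors = FALSE)
}

#' Module eigengenes
#'
#' Per module with at least 2 member OTUs present in the table: relative
#' abundances of the members are standardized per OTU across samples and
#' the first principal axis of the member x sample submatrix is taken as
#' the eigengene (one value per sample, unit variance), signed to
#' correlate positively with the module's mean standardized member
#' profile. Variance explained is the leading singular value's share of
#' the total.
#'
#' @param x an \linkS4class{OtuExperiment} (rarefied counts).
#' @param partition a \linkS4class{ModulePartition} over (a subset of)
#'   the table's taxa.
#' @return an \linkS4class{EigengeneResult}
#' @export
moduleEigengenes <- function(x, partition) {
    prop <- relativeAbundance(x)
    memb <- membership(partition)
    memb <- memb[names(memb) %in% rownames(prop)]
    mods <- sort(unique(memb))
    egList <- list()
    ve <- numeric(0)
    for (m in mods) {
        taxa <- names(memb)[memb == m]
        if (length(taxa) < 2) {
            warning("module ", m, " has fewer than 2 members in the ",
                    "table; skipped")
            next
        }
        Z <- t(scale(t(prop[taxa, , drop = FALSE])))  # per-OTU standardized
        Z[!is.finite(Z)] <- 0                          # constant profiles
        sv <- svd(Z)
        eg <- sv$v[, 1]
        eg <- eg / stats::sd(eg)
        meanProfile <- colMeans(Z)
        if (stats::sd(meanProfile) > 0 &&
            stats::cor(eg, meanProfile) < 0) eg <- -eg
        egList[[paste0("M", m)]] <- eg
        ve[paste0("M", m)] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (!length(egList)) stop("no module with >= 2 members in the table")
    E <- do.call(cbind, egList)
    rownames(E) <- colnames(prop)
    mc <- stats::cor(E)
    cl <- if (ncol(E) >= 3)
        stats::hclust(stats::as.dist(1 - mc), method = "average")
    else NULL
    new("EigengeneResult", eigengenes = E, varianceExplained = ve,
        moduleCor = mc, clustering = cl)
}

#' Pearson correlation between module eigengenes and metal concentrations
#'
#' @param eig an \linkS4class{EigengeneResult}
#' @param x an \linkS4class{OtuExperiment} carrying metal columns in
#'   colData (ug/L), or a samples x metals matrix; needs >= 10 samples
#'   with both values. Constant metal vectors are skipped with a message.
#' @return data.frame (module, metal, r, p); the eigengene supergroup
#'   clustering is carried in attribute \code{"clustering"}.
#' @export
eigengeneMetalCorrelation <- function(eig, x) {
    metals <- if (is(x, "OtuExperiment")) metalConcentrations(x) else
        as.matrix(x)
    if (is.null(metals)) stop("no metal concentrations available")
    E <- eigengenes(eig)
    common <- intersect(rownames(E), rownames(metals))
    out <- list()
    for (mod in colnames(E)) for (met in colnames(metals)) {
        ok <- common[!is.na(metals[common, met])]
        if (length(ok) < 10) next
        mv <- metals[ok, met]
        if (stats::sd(mv) == 0) {
            message("metal ", met, " is constant; pair skipped")
            next
        }
        ct <- stats::cor.test(E[ok, mod], mv, method = "pearson")
        out[[length(out) + 1]] <- data.frame(
            module = mod, metal = met, n = length(ok),
            r = unname(ct$estimate), p = ct$p.value,
            stringsAsFactors = FALSE)
    }
    if (!length(out)) stop("fewer than 10 samples with both eigengene ",
                           "and metal values")
    res <- do.call(rbind, out)
    attr(res, "clustering") <- eig@clustering
    res
}

#' Compare node sets of two networks
#'
#' Set algebra on node ids (shared/unshared counts, the Venn numbers) plus
#' the per-phylum composition of each network's nodes from their taxonomy
#' lineages.
#'
#' @param a,b \linkS4class{MicrobialNetwork}s with vertex \code{taxonomy}
#'   attributes (phylum fractions are NA without them).
#' @return list: counts (named vector sharedNodes, onlyA, onlyB,
#'   unshared) and phylumComposition (data.frame phylum, fractionA,
#'   fractionB).
#' @export
compareNetworks <- function(a, b) {
    na <- igraph::V(a@graph)$name
    nb <- igraph::V(b@graph)$name
    if (!length(na) || !length(nb)) stop("both networks must be non-empty")
    shared <- intersect(na, nb)
    counts <- c(sharedNodes = length(shared),
                onlyA = length(setdiff(na, nb)),
                onlyB = length(setdiff(nb, na)),
                unshared = length(setdiff(na, nb)) +
                    length(setdiff(nb, na)))
    phylumFrac <- function(net) {
        tax <- igraph::vertex_attr(net@graph, "taxonomy")
        if (is.null(tax)) return(NULL)
        ph <- parseLineages(tax)[, "phylum"]
        tb <- table(ph)
        tb / sum(tb)
    }
    fa <- phylumFrac(a)
    fb <- phylumFrac(b)
    comp <- NULL
    if (!is.null(fa) && !is.null(fb)) {
        phyla <- sort(unique(c(names(fa), names(fb))))
        comp <- data.frame(
            phylum = phyla,
            fractionA = as.numeric(fa[phyla]),
            fractionB = as.numeric(fb[phyla]))
        comp[is.na(comp)] <- 0
    }
    list(counts = counts, phylumComposition = comp)
}
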