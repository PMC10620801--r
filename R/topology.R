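## Topological index suite, power-law fit, and Maslov-Sneppen null
## ensembles. All indices are computed on the unweighted, sign-stripped
## simple graph; edge weights are only sign bookkeeping.

## Shortest-path counts from every source (unweighted BFS with
## path-count accumulation). Returns list(D = distances, S = path counts).
shortestPathCounts <- function(g) {
    n <- igraph::vcount(g)
    D <- igraph::distances(g)
    adj <- igraph::as_adj_list(g)
    adj <- lapply(adj, as.integer)
    S <- matrix(0, n, n)
    for (s in seq_len(n)) {
        d <- D[s, ]
        sig <- numeric(n)
        sig[s] <- 1
        ord <- order(d)
        ord <- ord[is.finite(d[ord])]
        for (w in ord) {
            if (w == s) next
            preds <- adj[[w]][d[adj[[w]]] == d[w] - 1]
            sig[w] <- sum(sig[preds])
        }
        S[s, ] <- sig
    }
    list(D = D, S = S)
}

## Stress centrality: number of shortest paths passing through each node
## (endpoints excluded), over unordered pairs.
stressCentrality <- function(g, sp = shortestPathCounts(g)) {
    n <- igraph::vcount(g)
    D <- sp$D
    S <- sp$S
    vapply(seq_len(n), function(v) {
        dv <- D[v, ]
        through <- outer(dv, dv, "+") == D & is.finite(D)
        W <- outer(S[v, ], S[v, ]) * through
        W[v, ] <- 0
        W[, v] <- 0
        diag(W) <- 0
        sum(W[upper.tri(W)])
    }, numeric(1))
}

## Freeman centralization: sum(max - c) over the same sum for the
## theoretical maximum, here the star graph on the same number of nodes.
freemanCentralization <- function(values, starValues) {
    num <- sum(max(values) - values)
    den <- sum(max(starValues) - starValues)
    if (den == 0) return(0)
    num / den
}

harmonicCloseness <- function(g) {
    D <- igraph::distances(g)
    n <- nrow(D)
    inv <- 1 / D
    diag(inv) <- 0
    rowSums(inv) / (n - 1)
}

## Krackhardt efficiency on the underlying undirected graph: 1 minus the
## fraction of surplus edges (beyond a spanning tree per component)
## relative to the maximum possible surplus.
krackhardtEfficiency <- function(g) {
    comp <- igraph::components(g)
    sizes <- comp$csize
    L <- igraph::ecount(g)
    minEdges <- sum(sizes - 1)
    maxEdges <- sum(sizes * (sizes - 1) / 2)
    if (maxEdges == minEdges) return(1)
    1 - (L - minEdges) / (maxEdges - minEdges)
}

#' Topological index suite for a network
#'
#' Computes the standard molecular-ecological-network index panel on the
#' unweighted graph: node/link counts, average degree (avgK = 2L/N),
#' average local clustering coefficient (degree < 2 contributes 0),
#' average geodesic distance GD over connected pairs, geodesic efficiency
#' E = mean(1/d) with 1/Inf = 0, harmonic geodesic distance HD = 1/E,
#' Freeman centralizations of degree/betweenness/stress/eigenvector/
#' (harmonic) closeness normalized by the star-graph maximum, density,
#' reciprocity (1 for undirected), transitivity, Krackhardt connectedness
#' and efficiency, hierarchy (0: undirected reachability is symmetric) and
#' LUBness (1: every connected pair of an undirected graph has a least
#' upper bound), modularity Q of the supplied partition, and the
#' power-law R-squared of the degree distribution (NA when fewer than 3
#' distinct degrees).
#'
#' @param net a \linkS4class{MicrobialNetwork} (or igraph graph).
#' @param partition optional \linkS4class{ModulePartition} (or named
#'   membership vector) for Q; when missing, Q is NA.
#' @return named numeric vector of indices.
#' @export
topologyIndices <- function(net, partition = NULL) {
    g <- if (is(net, "MicrobialNetwork")) net@graph else net
    n <- igraph::vcount(g)
    if (n < 2) stop("need at least 2 nodes")
    L <- igraph::ecount(g)
    deg <- igraph::degree(g)
    locCC <- igraph::transitivity(g, type = "localundirected",
                                  isolates = "zero")
    D <- igraph::distances(g)
    off <- upper.tri(D)
    finiteOff <- D[off][is.finite(D[off])]
    GD <- if (length(finiteOff)) mean(finiteOff) else NA_real_
    invD <- 1 / D[off]
    invD[!is.finite(invD)] <- 0
    E <- mean(invD)
    HD <- if (E > 0) 1 / E else Inf
    star <- igraph::make_star(n, mode = "undirected")
    sp <- shortestPathCounts(g)
    CD <- freemanCentralization(deg, igraph::degree(star))
    CB <- freemanCentralization(igraph::betweenness(g),
                                igraph::betweenness(star))
    CS <- freemanCentralization(stressCentrality(g, sp),
                                stressCentrality(star))
    CE <- freemanCentralization(abs(igraph::eigen_centrality(g)$vector),
                                abs(igraph::eigen_centrality(star)$vector))
    CCL <- freemanCentralization(harmonicCloseness(g),
                                 harmonicCloseness(star))
    dens <- 2 * L / (n * (n - 1))
    trans <- igraph::transitivity(g, type = "global")
    if (is.nan(trans)) trans <- 0
    comp <- igraph::components(g)
    reachable <- sum(comp$csize * (comp$csize - 1) / 2)
    con <- reachable / (n * (n - 1) / 2)
    Q <- NA_real_
    if (!is.null(partition)) {
        memb <- if (is(partition, "ModulePartition"))
            membership(partition) else partition
        Q <- igraph::modularity(g, memb[igraph::V(g)$name])
    }
    r2 <- tryCatch(powerlawFit(deg)[["r.squared"]],
                   error = function(e) NA_real_)
    c(N = n, L = L, avgK = 2 * L / n, avgCC = mean(locCC), GD = GD,
      E = E, HD = HD, CD = CD, CB = CB, CS = CS, CE = CE, CCL = CCL,
      D = dens, reciprocity = 1, Trans = trans, Con = con,
      efficiency = krackhardtEfficiency(g), hierarchy = 0, lubness = 1,
      Q = Q, R2powerlaw = r2)
}

#' Power-law fit of a degree distribution
#'
#' Least-squares fit of log(frequency) against log(degree) over the
#' non-zero degree bins.
#'
#' @param degrees integer degree sequence.
#' @return named vector: slope and r.squared.
#' @export
powerlawFit <- function(degrees) {
    degrees <- degrees[degrees > 0]
    tab <- table(degrees)
    if (length(tab) < 3)
        stop("power-law fit needs >= 3 distinct non-zero degrees")
    k <- as.numeric(names(tab))
    f <- as.numeric(tab)
    fit <- stats::lm(log(f) ~ log(k))
    ## summary.lm warns on an exactly perfect fit; R^2 = 1 is legitimate
    r2 <- suppressWarnings(summary(fit)$r.squared)
    c(slope = unname(stats::coef(fit)[2]), r.squared = r2)
}

#' Maslov-Sneppen degree-preserving rewiring
#'
#' Randomizes a network by repeated double-edge swaps — pick edges (a,b)
#' and (c,d), rewire to (a,d) and (c,b) — rejecting swaps that would
#' create self-loops or duplicate edges, so every node keeps its exact
#' degree. When no legal swap exists (all edges share one node, e.g. a
#' star) the input is returned with a warning.
#'
#' @param net a \linkS4class{MicrobialNetwork}
#' @param nSwapsPerEdge swap attempts per edge (default 100).
#' @param seed integer seed.
#' @return a rewired \linkS4class{MicrobialNetwork}
#' @export
maslovSneppen <- function(net, nSwapsPerEdge = 100, seed) {
    g <- net@graph
    L <- igraph::ecount(g)
    if (L < 2) stop("need at least 2 edges to rewire")
    el <- igraph::as_edgelist(g, names = FALSE)
    if (length(unique(c(el))) >= 2 &&
        any(vapply(unique(c(el)),
                   function(v) all(el[, 1] == v | el[, 2] == v),
                   logical(1)))) {
        warning("no legal degree-preserving swap exists; ",
                "returning the input network")
        return(net)
    }
    set.seed(childSeed(seed, "rewire"))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
        loops = FALSE, niter = nSwapsPerEdge * L))
    asNetwork(g2)
}

#' Degree-preserving null ensemble of topology indices
#'
#' Generates \code{k} independent Maslov-Sneppen rewirings, computes the
#' full index suite (with a fresh greedy-modularity partition) on each, and
#' summarizes every index as mean and SD over the ensemble, flagging the
#' empirical value as nonrandom when it falls outside mean +/- 2 SD.
#'
#' @param net a \linkS4class{MicrobialNetwork}
#' @param k ensemble size (>= 2), default 100.
#' @param seed integer seed.
#' @return data.frame (index, empirical, nullMean, nullSd, nonrandom) with
#'   the per-network index matrix in attribute \code{"ensemble"}.
#' @export
nullEnsemble <- function(net, k = 100, seed) {
    if (k < 2) stop("k must be >= 2")
    part <- greedyModularity(net)
    emp <- topologyIndices(net, part)
    idx <- matrix(NA_real_, k, length(emp),
                  dimnames = list(NULL, names(emp)))
    for (i in seq_len(k)) {
        rnet <- maslovSneppen(net, seed = childSeed(seed, paste0("ens", i)))
        rpart <- greedyModularity(rnet)
        idx[i, ] <- suppressWarnings(topologyIndices(rnet, rpart))
    }
    mu <- colMeans(idx)
    sdv <- apply(idx, 2, stats::sd)
    out <- data.frame(index = names(emp), empirical = unname(emp),
                      nullMean = unname(mu), nullSd = unname(sdv),
                      nonrandom = unname(abs(emp - mu) > 2 * sdv),
                      stringsAsFactors = FALSE)
    attr(out, "ensemble") <- idx
    out
}

#' Write a topology summary / null comparison as TSV
#'
#' @param x output of \code{\link{topologyIndices}} (named vector) or
#'   \code{\link{nullEnsemble}} (data.frame).
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTopology <- function(x, path) {
    df <- if (is.data.frame(x)) x else
        data.frame(index = names(x), empirical = unname(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
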