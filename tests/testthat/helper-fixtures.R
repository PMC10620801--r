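## Shared fixtures and independent brute-force oracles.

toyCounts <- function() {
    matrix(c(40, 30, 20, 10,
             5, 5, 60, 30,
             12, 0, 8, 80),
           nrow = 4, ncol = 3,
           dimnames = list(paste0("OTU", 1:4), paste0("S", 1:3)))
}

toyLineages <- function() {
    c("k__Bacteria;p__Firmicutes;c__Bacilli;o__;f__;g__Streptococcus;s__",
      "k__Bacteria;p__Firmicutes;c__Bacilli;o__;f__;g__Gemella;s__",
      "k__Bacteria;p__Actinobacteriota;c__;o__;f__;g__Rhodococcus;s__",
      "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__Delftia;s__")
}

toyOtu <- function() {
    OtuExperiment(toyCounts(), taxonomy = toyLineages(),
                  group = c("exposure", "exposure", "control"))
}

randomConnectedGraph <- function(n, seed) {
    set.seed(seed)
    repeat {
        g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.8))
        if (igraph::is_connected(g) && igraph::ecount(g) >= 2) break
    }
    igraph::V(g)$name <- paste0("n", seq_len(n))
    g
}

## ---- brute-force graph oracles (n <= ~10) ----

## all-pairs shortest paths by explicit enumeration of simple paths
brutePaths <- function(g) {
    n <- igraph::vcount(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    paths <- vector("list", 0)
    D <- matrix(Inf, n, n); diag(D) <- 0
    S <- matrix(0, n, n); diag(S) <- 1
    allPaths <- list()
    dfs <- function(path, target) {
        v <- path[length(path)]
        if (v == target) {
            allPaths[[length(allPaths) + 1]] <<- path
            return()
        }
        for (w in which(A[v, ] == 1))
            if (!w %in% path) dfs(c(path, w), target)
    }
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        allPaths <- list()
        dfs(s, t)
        if (length(allPaths)) {
            lens <- vapply(allPaths, length, integer(1)) - 1L
            D[s, t] <- D[t, s] <- min(lens)
            short <- allPaths[lens == min(lens)]
            S[s, t] <- S[t, s] <- length(short)
            attr(S, paste(s, t)) <- short
        }
    }
    list(D = D, S = S)
}

## brute-force betweenness and stress from the enumerated shortest paths
bruteCentralities <- function(g) {
    n <- igraph::vcount(g)
    bp <- brutePaths(g)
    btw <- numeric(n); str <- numeric(n)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        short <- attr(bp$S, paste(s, t))
        if (is.null(short)) next
        for (pth in short) {
            inner <- setdiff(pth, c(s, t))
            str[inner] <- str[inner] + 1
            btw[inner] <- btw[inner] + 1 / length(short)
        }
    }
    list(D = bp$D, S = bp$S, betweenness = btw, stress = str)
}

bruteClustering <- function(g) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    n <- nrow(A)
    loc <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] == 1)
        k <- length(nb)
        if (k < 2) { loc[v] <- 0; next }
        loc[v] <- sum(A[nb, nb]) / (k * (k - 1))
    }
    tri <- 0; trip <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
        if (i != j && j != k && i != k && A[i, j] && A[j, k]) {
            trip <- trip + 1
            if (A[i, k]) tri <- tri + 1
        }
    }
    list(local = loc, transitivity = if (trip > 0) tri / trip else 0)
}

## all set partitions of 1..n (Bell numbers; fine for n <= 8)
allPartitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    sub <- allPartitions(n - 1)
    out <- vector("list", 0)
    for (p in sub) {
        for (k in seq_along(p)) {
            q <- p
            q[[k]] <- c(q[[k]], n)
            out[[length(out) + 1]] <- q
        }
        out[[length(out) + 1]] <- c(p, list(n))
    }
    out
}

## direct Q = sum(e_mm - a_m^2) for a membership vector
directQ <- function(g, memb) {
    el <- igraph::as_edgelist(g, names = FALSE)
    m <- nrow(el)
    if (m == 0) return(0)
    mods <- sort(unique(memb))
    deg <- igraph::degree(g)
    q <- 0
    for (md in mods) {
        inM <- which(memb == md)
        emm <- sum(el[, 1] %in% inM & el[, 2] %in% inM) / m
        am <- sum(deg[inM]) / (2 * m)
        q <- q + emm - am^2
    }
    q
}

exhaustiveMaxQ <- function(g) {
    n <- igraph::vcount(g)
    best <- -Inf
    for (p in allPartitions(n)) {
        memb <- integer(n)
        for (k in seq_along(p)) memb[p[[k]]] <- k
        q <- directQ(g, memb)
        if (q > best) best <- q
    }
    best
}

## brute-force Zi/Pi from per-module link tallies
bruteZiPi <- function(g, memb) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    nodes <- igraph::V(g)$name
    memb <- memb[nodes]
    n <- length(nodes)
    mods <- sort(unique(memb))
    Zi <- Pi <- numeric(n)
    for (v in seq_len(n)) {
        k <- sum(A[v, ])
        kim <- vapply(mods, function(m) sum(A[v, memb == m]), numeric(1))
        Pi[v] <- if (k == 0) 0 else 1 - sum((kim / k)^2)
        own <- which(mods == memb[v])
        inMod <- which(memb == memb[v])
        kOwn <- vapply(inMod, function(u) sum(A[u, memb == memb[v]]),
                       numeric(1))
        sdv <- stats::sd(kOwn)
        Zi[v] <- if (is.na(sdv) || sdv == 0) 0 else
            (sum(A[v, memb == memb[v]]) - mean(kOwn)) / sdv
    }
    data.frame(node = nodes, Zi = Zi, Pi = Pi)
}

## ANOSIM R statistic from its definition
anosimRstat <- function(d, g) {
    dv <- as.vector(d)
    rk <- rank(dv)
    n <- attr(d, "Size")
    pr <- utils::combn(n, 2)
    within <- g[pr[1, ]] == g[pr[2, ]]
    (mean(rk[!within]) - mean(rk[within])) / (length(dv) / 2)
}

## adjusted Rand index between two labelings
ariIndex <- function(a, b) {
    tb <- table(a, b)
    sumij <- sum(choose(tb, 2))
    ai <- sum(choose(rowSums(tb), 2))
    bj <- sum(choose(colSums(tb), 2))
    nn <- choose(sum(tb), 2)
    expd <- ai * bj / nn
    mx <- (ai + bj) / 2
    if (mx == expd) return(1)
    (sumij - expd) / (mx - expd)
}

## quick planted-model pipeline for recovery tests
recoverOnce <- function(seed, nTaxa = 300, nModules = 6, depth = 5000,
                        nPerGroup = 60) {
    pm <- plantNetwork(nTaxa, nModules, intraDensity = 1,
                       negativeFraction = 0.1, seed = seed,
                       backgroundFraction = 0.7,
                       nSamplesPerGroup = c(exposure = as.integer(nPerGroup),
                                            control = as.integer(nPerGroup)))
    x <- simulateCounts(pm, depth = depth, seed = seed + 1)
    x <- prevalenceFilter(x, 0.10)     # as in the full pipeline
    fit <- sparcc(x, nResamples = 20, seed = seed + 2)
    fit <- sparccPvalues(x, fit, nPermutations = 100, seed = seed + 3)
    scan <- rmtSelectCutoff(fit)
    net <- buildNetwork(fit, scan, taxonomy = taxonomy(x))
    ids <- pm@taxonIds
    et <- pm@edgeTruth
    keep <- ids[et$i] %in% rownames(x) & ids[et$j] %in% rownames(x)
    et <- et[keep, , drop = FALSE]
    trueKeys <- paste(ids[et$i], ids[et$j])
    estKeys <- paste(net@edges$source, net@edges$target)
    part <- greedyModularity(net)
    nodes <- igraph::V(net@graph)$name
    planted <- pm@moduleAssignment[match(nodes, pm@taxonIds)]
    list(precision = mean(estKeys %in% trueKeys),
         recall = mean(trueKeys %in% estKeys),
         ari = ariIndex(planted, membership(part)[nodes]),
         cutoff = scan@selected)
}
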