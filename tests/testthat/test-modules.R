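test_that("greedy modularity resolves canonical modular graphs", {
    ## two 4-cliques joined by one edge -> the two cliques
    g <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
    g <- igraph::add_edges(g, c(1, 5))
    igraph::V(g)$name <- paste0("n", 1:8)
    p <- greedyModularity(g)
    expect_identical(length(p@sizes), 2L)
    expect_identical(unname(membership(p)[c("n1", "n2", "n3", "n4")]),
                     rep(1L, 4))
    expect_equal(p@modularity, exhaustiveMaxQ(g), tolerance = 1e-12)
    ## two disconnected equal cliques: Q = 2 (0.5 - 0.25) = 0.5
    g2 <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
    igraph::V(g2)$name <- paste0("n", 1:8)
    expect_equal(greedyModularity(g2)@modularity, 0.5)
    ## complete graph: one module, Q = 0
    g3 <- igraph::make_full_graph(6)
    igraph::V(g3)$name <- paste0("n", 1:6)
    p3 <- greedyModularity(g3)
    expect_identical(length(p3@sizes), 1L)
    expect_equal(p3@modularity, 0)
    ## edgeless graph: all singletons, Q = 0
    g4 <- igraph::make_empty_graph(5, directed = FALSE)
    igraph::V(g4)$name <- paste0("n", 1:5)
    p4 <- greedyModularity(g4)
    expect_identical(length(p4@sizes), 5L)
    expect_equal(p4@modularity, 0)
})

test_that("reported Q matches igraph's evaluation of the same partition", {
    for (seed in 1:8) {
        g <- randomConnectedGraph(sample(6:12, 1), 200 + seed)
        p <- greedyModularity(g)
        expect_equal(p@modularity,
                     igraph::modularity(g, membership(p)[
                         igraph::V(g)$name]),
                     tolerance = 1e-12)
        ## module count bookkeeping
        expect_equal(sum(p@sizes), igraph::vcount(g))
        expect_identical(modulesLargerThan(p, 0),
                         length(p@sizes))
    }
})

test_that("Zi-Pi follows its closed forms and the brute-force recount", {
    ## hand-built 10-node two-module graph
    g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
    g <- igraph::add_edges(g, c(1, 6, 2, 7))
    igraph::V(g)$name <- paste0("n", 1:10)
    net <- asNetwork(g)
    part <- greedyModularity(net)
    roles <- ziPi(net, part)
    ## all links inside the own module -> Pi = 0
    expect_equal(roles$Pi[roles$node == "n3"], 0)
    ## node with links split across modules: n1 has 4 own + 1 other of 5
    expect_equal(roles$Pi[roles$node == "n1"], 1 - (4 / 5)^2 - (1 / 5)^2)
    bf <- bruteZiPi(g, membership(part))
    expect_equal(roles$Zi, bf$Zi, tolerance = 1e-12)
    expect_equal(roles$Pi, bf$Pi, tolerance = 1e-12)
    ## role counts cover all nodes; relabeling nodes leaves roles intact
    expect_identical(nrow(roles), 10L)
    perm <- sample(10)
    g5 <- igraph::permute(g, perm)
    net5 <- asNetwork(g5)
    roles5 <- ziPi(net5, greedyModularity(net5))
    expect_identical(sort(table(roles$role)), sort(table(roles5$role)))
    ## even split across 2 modules: Pi = 0.5
    gl <- igraph::graph_from_literal(a - b, a - c)
    memb <- stats::setNames(c(1L, 1L, 2L), c("a", "b", "c"))
    ## give b its own context: use explicit partition covering all nodes
    rl <- ziPi(asNetwork(gl),
               new("ModulePartition", membership = memb,
                   modularity = 0, sizes = c(2L, 1L)))
    expect_equal(rl$Pi[rl$node == "a"], 0.5)
})

test_that("module eigengenes capture rank-1 modules and fix the sign", {
    set.seed(31)
    n <- 40
    base <- rnorm(n)
    cnt <- rbind(
        m1a = round(200 + 50 * base),
        m1b = round(400 + 100 * base),
        m1c = round(100 + 25 * base),
        m2a = round(100 + 40 * rnorm(n)),
        m2b = round(150 + 40 * rnorm(n)),
        filler = rep(500, n))
    cnt[cnt < 1] <- 1
    colnames(cnt) <- paste0("S", seq_len(n))
    x <- OtuExperiment(cnt)
    memb <- stats::setNames(c(1L, 1L, 1L, 2L, 2L),
                            c("m1a", "m1b", "m1c", "m2a", "m2b"))
    part <- new("ModulePartition", membership = memb, modularity = 0,
                sizes = c(3L, 2L))
    eig <- moduleEigengenes(x, part)
    E <- eigengenes(eig)
    expect_identical(colnames(E), c("M1", "M2"))
    expect_equal(unname(apply(E, 2, var)), c(1, 1), tolerance = 1e-9)
    ## members of module 1 are (nearly) one profile: variance explained ~ 1
    expect_gt(eig@varianceExplained[["M1"]], 0.95)
    ## independent members: variance explained near 1/2
    expect_lt(eig@varianceExplained[["M2"]], 0.95)
    ## sign contract: eigengene correlates positively with the mean
    ## standardized member profile
    prop <- relativeAbundance(x)
    for (mod in c(1, 2)) {
        taxa <- names(memb)[memb == mod]
        Z <- t(scale(t(prop[taxa, ])))
        expect_gt(cor(E[, paste0("M", mod)], colMeans(Z)), 0)
    }
    ## modules with < 2 present members are skipped with a warning
    memb2 <- stats::setNames(c(1L, 1L, 2L), c("m1a", "m1b", "m2a"))
    expect_warning(
        moduleEigengenes(x, new("ModulePartition", membership = memb2,
                                modularity = 0, sizes = c(2L, 1L))),
        "skipped")
})

test_that("independent member profiles spread variance ~ 1/n", {
    set.seed(32)
    ve <- replicate(20, {
        ## 5 independent members inside a 50-taxon table, so closure
        ## barely couples their relative abundances
        cnt <- matrix(rpois(50 * 1000, 200), 50, 1000,
                      dimnames = list(paste0("t", 1:50),
                                      paste0("S", 1:1000)))
        memb <- stats::setNames(rep(1L, 5), paste0("t", 1:5))
        part <- new("ModulePartition", membership = memb,
                    modularity = 0, sizes = 5L)
        moduleEigengenes(OtuExperiment(cnt), part)@varianceExplained
    })
    ## leading-share of an isotropic 5 x n matrix tends to 1/5 from above
    expect_lt(abs(mean(ve) - 1 / 5), 0.06)
})

test_that("eigengene-metal correlations behave at both extremes", {
    set.seed(33)
    n <- 50
    base <- rnorm(n)
    cnt <- rbind(a = round(200 + 60 * base), b = round(300 + 90 * base),
                 c = rep(400, n))
    cnt[cnt < 1] <- 1
    colnames(cnt) <- paste0("S", seq_len(n))
    x <- OtuExperiment(cnt)
    memb <- stats::setNames(c(1L, 1L), c("a", "b"))
    part <- new("ModulePartition", membership = memb, modularity = 0,
                sizes = 2L)
    eig <- moduleEigengenes(x, part)
    met <- cbind(Exact = as.vector(eigengenes(eig)[, "M1"]) + 5,
                 Flat = rep(3, n))
    rownames(met) <- colnames(cnt)
    expect_message(res <- eigengeneMetalCorrelation(eig, met),
                   "constant")
    expect_equal(res$r[res$metal == "Exact"], 1, tolerance = 1e-9)
    expect_false("Flat" %in% res$metal)
    ## independent metals: roughly nominal false positive rate
    set.seed(34)
    hits <- replicate(200, {
        met2 <- cbind(X = rnorm(n))
        rownames(met2) <- colnames(cnt)
        eigengeneMetalCorrelation(eig, met2)$p < 0.05
    })
    expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("network comparison counts nodes and phylum fractions", {
    mk <- function(ids, phyla) {
        g <- igraph::make_ring(length(ids))
        igraph::V(g)$name <- ids
        igraph::V(g)$taxonomy <- sprintf("k__Bacteria;p__%s;c__;o__;f__;g__;s__",
                                         phyla)
        asNetwork(g)
    }
    a <- mk(c("x1", "x2", "x3"), c("Firmicutes", "Firmicutes",
                                   "Bacteroidota"))
    b <- mk(c("x3", "x4", "x5", "x6"), rep("Proteobacteria", 4))
    cmp <- compareNetworks(a, b)
    expect_identical(unname(cmp$counts["sharedNodes"]), 1L)
    expect_identical(unname(cmp$counts["unshared"]), 5L)
    expect_equal(sum(cmp$phylumComposition$fractionA), 1)
    expect_equal(sum(cmp$phylumComposition$fractionB), 1)
    ## identical networks share everything
    cmp2 <- compareNetworks(a, a)
    expect_identical(unname(cmp2$counts["unshared"]), 0L)
    ## disjoint 3 + 4
    c3 <- mk(c("y1", "y2", "y3"), rep("Firmicutes", 3))
    cmp3 <- compareNetworks(c3, b)
    expect_identical(unname(cmp3$counts["sharedNodes"]), 0L)
    expect_identical(unname(cmp3$counts["unshared"]), 7L)
})
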