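test_that("alpha diversity matches closed forms", {
    ## uniform community: Shannon = ln S, Simpson = 1 - 1/S
    cnt <- matrix(1, 10, 1, dimnames = list(paste0("O", 1:10), "S1"))
    a <- alphaDiversity(OtuExperiment(cnt))
    expect_equal(a$shannon, log(10), tolerance = 1e-12)
    expect_equal(a$simpson, 0.9, tolerance = 1e-12)
    expect_identical(a$sobs, 10L)
    ## Chao1 = S + F1(F1-1)/(2(F2+1)): counts (5,3,1,1) -> 4 + 2/2 = 5
    cnt2 <- matrix(c(5, 3, 1, 1), 4, 1,
                   dimnames = list(paste0("O", 1:4), "S1"))
    a2 <- alphaDiversity(OtuExperiment(cnt2))
    expect_equal(a2$chao1, 5)
    ## no singletons: Chao1 = Sobs, and ACE >= Sobs always
    cnt3 <- matrix(c(5, 3, 2, 2), 4, 1,
                   dimnames = list(paste0("O", 1:4), "S1"))
    a3 <- alphaDiversity(OtuExperiment(cnt3))
    expect_equal(a3$chao1, 4)
    expect_gte(a3$ace, a3$sobs)
    expect_gte(a2$chao1, a2$sobs)
    expect_error(alphaDiversity(OtuExperiment(
        matrix(c(1, 0), 1, 2, dimnames = list("O1", c("a", "b"))))),
        "empty sample")
})

test_that("beta distances satisfy metric contracts and hand values", {
    x <- toyOtu()
    tr <- simulateTree(rownames(x), seed = 3)
    for (m in c("bray", "unweighted-unifrac", "weighted-unifrac")) {
        d <- as.matrix(betaDistance(x, m, tree = tr))
        expect_equal(unname(diag(d)), rep(0, 3))
        expect_equal(d, t(d))
        if (grepl("unifrac", m))
            expect_true(all(d >= 0 & d <= 1 + 1e-12))
    }
    ## identical samples are at distance zero in every metric
    same <- OtuExperiment(matrix(c(3, 7, 3, 7), 2, 2,
                                 dimnames = list(c("A", "B"),
                                                 c("s1", "s2"))))
    tr2 <- "((A:1,B:2):0.5);"
    for (m in c("bray", "unweighted-unifrac", "weighted-unifrac"))
        expect_equal(max(as.matrix(suppressWarnings(
            betaDistance(same, m, tree = tr2)))), 0, tolerance = 1e-12)
    ## hand-computed 3-leaf tree: ((A:1,B:2):3,C:4)
    cnt <- matrix(c(5, 5, 0, 0, 5, 5), 3, 2,
                  dimnames = list(c("A", "B", "C"), c("S1", "S2")))
    oe <- OtuExperiment(cnt)
    tr3 <- "((A:1,B:2):3,C:4);"
    ## shared branches B(2) + AB(3); unique A(1) + C(4); total 10
    expect_equal(as.vector(betaDistance(oe, "unweighted-unifrac",
                                        tr3)), 0.5)
    ## weighted: sum b|pA-pB| = 4 over sum b(pA+pB) = 9
    expect_equal(as.vector(betaDistance(oe, "weighted-unifrac", tr3)),
                 4 / 9, tolerance = 1e-12)
    ## disjoint clades sharing only the root: unweighted UniFrac = 1
    cnt4 <- matrix(c(5, 0, 0, 5), 2, 2,
                   dimnames = list(c("A", "C"), c("S1", "S2")))
    expect_equal(as.vector(betaDistance(OtuExperiment(cnt4),
                                        "unweighted-unifrac",
                                        "(A:1,C:4);")), 1)
    ## taxa missing from the tree are named in the error
    expect_error(betaDistance(oe, "unweighted-unifrac", "(A:1,B:2);"),
                 "C")
})

test_that("PCoA reproduces planar configurations and the dense solver", {
    set.seed(11)
    pts <- matrix(rnorm(20), 10, 2)
    d <- dist(pts)
    ord <- pcoaOrdination(d)
    ## classical MDS identity: recovered inter-point distances match
    rec <- dist(ord$coordinates[, 1:2])
    expect_equal(as.vector(rec), as.vector(d), tolerance = 1e-8)
    ## eigenvalues equal those of the doubly centered -D^2/2 matrix
    D <- as.matrix(d)
    n <- nrow(D)
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% D^2 %*% J
    expect_equal(sort(ord$eigenvalues), sort(eigen(B)$values),
                 tolerance = 1e-8)
    ## variance fractions use positive eigenvalues only
    pos <- ord$eigenvalues[ord$eigenvalues > 0]
    expect_equal(sum(ord$varianceExplained[ord$eigenvalues > 0]), 1,
                 tolerance = 1e-12)
    ## degenerate all-zero distances
    z <- pcoaOrdination(matrix(0, 4, 4))
    expect_equal(z$eigenvalues, rep(0, 4), tolerance = 1e-10)
    expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2)),
                 "symmetric")
})

test_that("ANOSIM matches its definition and the exhaustive oracle", {
    set.seed(3)
    pts <- matrix(rnorm(12), 6, 2)
    pts[4:6, ] <- pts[4:6, ] + 3
    d <- dist(pts)
    g <- rep(c("a", "b"), each = 3)
    an <- anosimTest(d, g, nPerm = 999, seed = 5)
    expect_equal(an$R, anosimRstat(d, g), tolerance = 1e-12)
    ## complete separation: R = 1
    expect_equal(an$R, 1)
    ## exhaustive permutation p over all 20 label assignments
    combs <- utils::combn(6, 3)
    Rs <- apply(combs, 2, function(ix) {
        gg <- rep("b", 6); gg[ix] <- "a"
        anosimRstat(d, gg)
    })
    expect_equal(an$p, mean(Rs >= an$R - 1e-12))
    ## null: shuffled labels give R near 0, and R bounded in [-1, 1]
    set.seed(7)
    vals <- replicate(30, {
        dd <- dist(matrix(rnorm(24), 12, 2))
        anosimTest(dd, sample(rep(c("a", "b"), 6)), nPerm = 99,
                   seed = 1)$R
    })
    expect_lt(abs(mean(vals)), 0.15)
    expect_true(all(vals >= -1 & vals <= 1))
    expect_error(anosimTest(d, c("a", rep("b", 5)), seed = 1),
                 ">= 2")
})

test_that("rank-sum group tests are correct, flagged, and BH-adjusted", {
    set.seed(21)
    f <- rbind(shifted = c(rnorm(10), rnorm(10) + 10),
               flat = rep(1, 20),
               noise = rnorm(20))
    g <- rep(c("a", "b"), each = 10)
    res <- groupDifferenceTest(f, g)
    expect_lt(res$q[res$feature == "shifted"], 0.001)
    expect_identical(res$p[res$feature == "flat"], 1)
    expect_true(res$constant[res$feature == "flat"])
    ## BH step-up on (0.01, 0.02, 0.03, 0.04) -> all 0.04
    expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    expect_error(groupDifferenceTest(f, rep("a", 20)), "two groups")
})

test_that("Spearman metal correlations equal the rank-Pearson definition", {
    set.seed(5)
    ab <- matrix(runif(24), 2, 12,
                 dimnames = list(c("g1", "g2"), paste0("S", 1:12)))
    ab <- sweep(ab, 2, colSums(ab), "/")
    met <- cbind(Cd = exp(ab["g1", ] * 10),      # monotone in g1
                 Pb = runif(12), Hg = rep(2, 12))
    rownames(met) <- colnames(ab)
    res <- spearmanMetalCorrelation(ab, met)
    expect_equal(res$rho[res$genus == "g1" & res$metal == "Cd"], 1)
    ## definitional oracle: Pearson correlation of the rank vectors
    byHand <- cor(rank(ab["g2", ]), rank(met[, "Pb"]))
    expect_equal(res$rho[res$genus == "g2" & res$metal == "Pb"], byHand,
                 tolerance = 1e-12)
    ## all-tied metal -> rho undefined, reported as NA
    expect_true(all(is.na(res$rho[res$metal == "Hg"])))
    expect_error(spearmanMetalCorrelation(ab[, 1:5], met[1:5, ]),
                 ">= 10")
})
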