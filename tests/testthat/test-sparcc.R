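## Fixture: counts from a known basis covariance with one strong pair.
sparccFixture <- function(n = 200, seed = 4, rho = 0.9, p = 32,
                          depth = 3000) {
    C <- diag(p)
    C[1, 2] <- C[2, 1] <- rho
    set.seed(seed)
    Z <- MASS::mvrnorm(n, mu = rep(2, p), Sigma = C)
    cnt <- apply(Z, 1, function(z) {
        w <- exp(z)
        stats::rmultinom(1, depth, w / sum(w))
    })
    rownames(cnt) <- paste0("t", seq_len(p))
    colnames(cnt) <- paste0("s", seq_len(n))
    cnt
}

test_that("sparcc output is a valid correlation matrix", {
    cnt <- sparccFixture(n = 40)
    fit <- sparcc(cnt, nResamples = 5, seed = 1)
    r <- correlations(fit)
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, nrow(r)))
    expect_true(all(abs(r) <= 1))
    expect_error(sparcc(cnt[1:3, ], seed = 1), "4 taxa")
    expect_error(sparcc(cnt[, 1:5], seed = 1), "10 samples")
})

test_that("sparcc recovers a strong planted pair and stays quiet on null", {
    cnt <- sparccFixture(n = 500, rho = 0.9)
    fit <- sparcc(cnt, nResamples = 20, seed = 2)
    expect_equal(correlations(fit)[1, 2], 0.9, tolerance = 0.1)
    ## shuffled-sample null: off-diagonal correlations near zero
    set.seed(3)
    cnt0 <- t(apply(cnt[, 1:200], 1, sample))
    fit0 <- sparcc(cnt0, nResamples = 5, seed = 3)
    r0 <- correlations(fit0)
    expect_lt(mean(abs(r0[upper.tri(r0)])), 0.1)
})

test_that("sparcc is invariant to per-sample count scaling", {
    cnt <- sparccFixture(n = 60)
    fitA <- sparcc(cnt, nResamples = 0, seed = 5)
    cnt2 <- cnt
    cnt2[, 1:10] <- cnt2[, 1:10] * 10
    fitB <- sparcc(cnt2, nResamples = 0, seed = 5)
    expect_lt(max(abs(correlations(fitA) - correlations(fitB))), 0.05)
})

test_that("permutation p-values are bounded, calibrated and stable", {
    cnt <- sparccFixture(n = 120, rho = 0.9, p = 12, depth = 2000)
    fit <- sparcc(cnt, nResamples = 10, seed = 6)
    fit <- sparccPvalues(cnt, fit, nPermutations = 100, seed = 7)
    ut <- upper.tri(fit@p)
    expect_true(all(fit@p[ut] > 0 & fit@p[ut] <= 1))
    ## the planted edge is significant, the null pairs mostly are not
    expect_lt(fit@q[1, 2], 0.05)
    others <- fit@q[ut][-1]
    expect_gt(mean(others > 0.05), 0.8)
    ## doubling the permutations leaves q<0.05 decisions unchanged
    fit2 <- sparccPvalues(cnt, fit, nPermutations = 200, seed = 7)
    expect_identical(fit@q[ut] < 0.05, fit2@q[ut] < 0.05)
    expect_error(sparccPvalues(cnt, fit, nPermutations = 50, seed = 1),
                 ">= 100")
})

test_that("RMT scan distinguishes GOE noise from modular structure", {
    ## GOE matrix: Wigner-Dyson spacings (chi2_Poisson > chi2_WD)
    set.seed(8)
    n <- 400
    M <- matrix(rnorm(n * n), n, n)
    M <- (M + t(M)) / sqrt(2 * n)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    s <- microMEN:::unfoldSpacings(ev)
    expect_gt(microMEN:::nnsdChisq(s, microMEN:::poissonPdf),
              microMEN:::nnsdChisq(s, microMEN:::wignerPdf))
    ## independent levels: Poisson wins
    s2 <- microMEN:::unfoldSpacings(sort(runif(400)))
    expect_lt(microMEN:::nnsdChisq(s2, microMEN:::poissonPdf),
              microMEN:::nnsdChisq(s2, microMEN:::wignerPdf))
    ## block-diagonal signal + weak noise: the selected cut-off separates
    ## noise from blocks, retaining every planted edge
    set.seed(9)
    p <- 120
    R <- diag(p)
    for (b in 0:3) R[b * 10 + 1:10, b * 10 + 1:10] <- 0.7
    diag(R) <- 1
    noise <- matrix(rnorm(p * p, 0, 0.08), p, p)
    noise <- (noise + t(noise)) / 2
    R2 <- pmin(pmax(R + noise, -1), 1)
    diag(R2) <- 1
    scan <- rmtSelectCutoff(R2, minEigen = 15)
    expect_true(scan@selected >= 0.3 && scan@selected < 0.7)
    ## degenerate spectrum: failure path
    expect_error(rmtSelectCutoff(diag(100)), "transition|degenerate")
    expect_error(rmtSelectCutoff(R2, grid = c(0.5, 0.4)), "grid")
})

test_that("network construction applies the cut-off and FDR rule exactly", {
    r <- diag(4)
    r[1, 2] <- r[2, 1] <- 0.50
    r[1, 3] <- r[3, 1] <- 0.40
    rownames(r) <- colnames(r) <- paste0("O", 1:4)
    q <- matrix(0.001, 4, 4, dimnames = dimnames(r))
    fit <- new("SparccFit", r = r, p = q, q = q, nResamples = 1L,
               nPermutations = 100L)
    net <- buildNetwork(fit, pinCutoff(0.45))
    expect_equal(igraph::vcount(net@graph), 2)
    expect_identical(nrow(net@edges), 1L)
    expect_identical(net@edges$source, "O1")
    expect_identical(net@edges$target, "O2")
    ## everything below the cut-off: explicit empty-network failure
    expect_error(buildNetwork(fit, pinCutoff(0.6)), "empty network")
    ## q above threshold kills the edge too
    fit@q <- matrix(0.2, 4, 4, dimnames = dimnames(r))
    expect_error(buildNetwork(fit, pinCutoff(0.45)), "empty network")
})

test_that("edge sets shrink monotonically in cut-off and FDR threshold", {
    cnt <- sparccFixture(n = 150, rho = 0.9, p = 16, depth = 2000)
    fit <- sparcc(cnt, nResamples = 5, seed = 10)
    fit <- sparccPvalues(cnt, fit, nPermutations = 100, seed = 11)
    edgeCount <- function(cut, qm) tryCatch(
        nrow(buildNetwork(fit, pinCutoff(cut), qMax = qm)@edges),
        error = function(e) 0)
    cuts <- c(0.2, 0.4, 0.6, 0.8)
    counts <- vapply(cuts, edgeCount, numeric(1), qm = 0.2)
    expect_true(all(diff(counts) <= 0))
    qs <- c(0.2, 0.1, 0.05, 0.01)
    countsQ <- vapply(qs, function(qm) edgeCount(0.2, qm), numeric(1))
    expect_true(all(diff(countsQ) <= 0))
})

test_that("positive-edge tally reports the exposure-network percentage", {
    ## 56 edges of which 55 positive -> 98.21% positive
    p <- 57
    r <- diag(p)
    for (i in 1:55) r[i, i + 1] <- r[i + 1, i] <- 0.6
    r[56, 57] <- r[57, 56] <- -0.6
    rownames(r) <- colnames(r) <- paste0("O", 1:p)
    q <- matrix(1e-4, p, p, dimnames = dimnames(r))
    fit <- new("SparccFit", r = r, p = q, q = q, nResamples = 1L,
               nPermutations = 100L)
    net <- buildNetwork(fit, pinCutoff(0.45))
    s <- edgeSignSummary(net)
    expect_identical(unname(s[c("positive", "negative")]), c(55, 1))
    expect_equal(unname(round(s["positivePct"], 2)), 98.21)
})
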