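## Random-matrix-theory cut-off selection.
##
## A correlation matrix dominated by noise has eigenvalue nearest-neighbour
## spacings following the Wigner-Dyson (GOE) law; once thresholding removes
## the correlated noise and leaves modular signal, spacings become Poisson.
## The transition point of the nearest-neighbour spacing distribution
## (NNSD) defines the cut-off.

## Unfold a spectrum: map eigenvalues through a smooth fit of the
## cumulative spectral density so spacings have unit mean; degenerate
## eigenvalues are collapsed first (their zero spacings carry no
## information about the bulk statistics).
unfoldSpacings <- function(ev, degree = 9, tol = 1e-8) {
    ev <- sort(ev)
    ev <- ev[c(TRUE, diff(ev) > tol)]
    n <- length(ev)
    if (n < 20) return(NULL)
    deg <- min(degree, n - 2)
    cdf <- (seq_len(n) - 0.5) / n
    fit <- stats::lm(cdf ~ poly(ev, deg))
    unfolded <- n * stats::fitted(fit)
    s <- diff(unfolded)
    s[s < 0] <- 0
    s / mean(s)
}

## Chi-square distance of observed spacings to a theoretical pdf over
## fixed bins on [0, 3] (overflow pooled into the last bin).
nnsdChisq <- function(s, pdf, nBins = 25) {
    br <- seq(0, 3, length.out = nBins + 1)
    obs <- tabulate(pmin(findInterval(pmin(s, 3 - 1e-12), br,
                                      rightmost.closed = TRUE), nBins),
                    nBins)
    mids <- (br[-1] + br[-length(br)]) / 2
    expd <- pdf(mids) * diff(br) * length(s)
    sum((obs - expd)^2 / pmax(expd, 0.5))
}

poissonPdf <- function(s) exp(-s)
wignerPdf <- function(s) (pi * s / 2) * exp(-pi * s^2 / 4)

#' Select a correlation cut-off by random matrix theory
#'
#' For each candidate cut-off, entries of the correlation matrix below it
#' (in absolute value) are zeroed, the eigenvalue spectrum is unfolded
#' through a smooth (polynomial degree 9) cumulative-density fit, and the
#' nearest-neighbour spacing distribution is compared by chi-square
#' distance to the Poisson law \eqn{e^{-s}} (modular signal) and the
#' Wigner-Dyson law \eqn{(\pi s/2) e^{-\pi s^2/4}} (correlated noise).
#' The selected cut-off is the smallest grid point whose NNSD is closer to
#' Poisson.
#'
#' @param x a \linkS4class{SparccFit} or a symmetric correlation matrix.
#' @param grid strictly increasing candidate cut-offs in (0, 1).
#' @param minEigen minimum non-degenerate eigenvalues needed to evaluate a
#'   cut-off (default 20).
#' @return an \linkS4class{RmtScan}
#' @export
rmtSelectCutoff <- function(x, grid = seq(0.30, 0.95, by = 0.01),
                            minEigen = 20) {
    r <- if (is(x, "SparccFit")) x@r else as.matrix(x)
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
        stop("correlation matrix must be symmetric")
    if (any(grid <= 0) || any(grid >= 1) || any(diff(grid) <= 0))
        stop("grid must be strictly increasing within (0, 1)")
    nG <- length(grid)
    chiP <- chiW <- rep(NA_real_, nG)
    nE <- integer(nG)
    for (k in seq_len(nG)) {
        A <- r
        A[abs(A) < grid[k]] <- 0
        diag(A) <- 1
        ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
        s <- unfoldSpacings(ev)
        nE[k] <- if (is.null(s)) 0L else length(s) + 1L
        if (is.null(s) || length(s) < minEigen) next
        chiP[k] <- nnsdChisq(s, poissonPdf)
        chiW[k] <- nnsdChisq(s, wignerPdf)
    }
    ok <- which(is.finite(chiP) & is.finite(chiW) & chiP < chiW)
    if (!length(ok))
        stop("no Wigner-Dyson to Poisson transition found on the grid; ",
             "widen the grid or check that the matrix has enough ",
             "non-degenerate structure")
    sel <- grid[ok[1]]
    new("RmtScan", grid = grid, chiPoisson = chiP, chiWigner = chiW,
        nEigen = nE, selected = sel)
}

#' Pin the correlation cut-off without scanning
#'
#' Returns an \linkS4class{RmtScan} with a fixed cut-off, for reproducing
#' runs whose threshold is already known (e.g. 0.45).
#'
#' @param cutoff the cut-off to pin.
#' @return an \linkS4class{RmtScan}
#' @export
pinCutoff <- function(cutoff) {
    new("RmtScan", grid = cutoff, chiPoisson = NA_real_,
        chiWigner = NA_real_, nEigen = NA_integer_, selected = cutoff)
}
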