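## SparCC: basis correlations from compositional counts.
##
## The estimator works on the log-ratio variation matrix
## T_ij = var(log(x_i / x_j)), which is invariant to per-sample closure.
## Under a sparsity assumption the per-taxon basis variances omega_i^2
## solve the linear system M w = t with t_i = sum_j T_ij,
## M = (p - 2) I + J, after which
## r_ij = (omega_i^2 + omega_j^2 - T_ij) / (2 omega_i omega_j).
## Strongly correlated pairs violate the sparsity assumption, so the
## strongest pair above an exclusion threshold is iteratively removed from
## the system and the variances re-solved.

## Core estimate from one fraction matrix (taxa x samples).
sparccCore <- function(frac, exclusionIters = 10,
                       exclusionThreshold = 0.8) {
    p <- nrow(frac)
    lf <- log(frac)
    C <- stats::cov(t(lf))
    if (any(!is.finite(C))) stop("non-finite log-ratio variation matrix")
    v <- diag(C)
    Tm <- outer(v, rep(1, p)) + outer(rep(1, p), v) - 2 * C
    diag(Tm) <- 0
    incl <- matrix(TRUE, p, p)          # pair included in the system
    diag(incl) <- FALSE
    solveR <- function() {
        d <- rowSums(incl)
        M <- incl * 1
        diag(M) <- d
        tv <- rowSums(Tm * incl)
        w2 <- tryCatch(solve(M, tv), error = function(e)
            stop("basis variance system is singular: ", conditionMessage(e)))
        if (all(w2 <= 0)) stop("all basis variances non-positive")
        ## a non-positive solved variance means the taxon's log fraction
        ## is essentially constant (e.g. all-zero counts): its basis
        ## correlations are uninformative, not +/-1
        degenerate <- w2 <= 0
        w2[degenerate] <- min(w2[!degenerate])
        w <- sqrt(w2)
        r <- (outer(w2, w2, "+") - Tm) / (2 * outer(w, w))
        r[r > 1] <- 1
        r[r < -1] <- -1
        r[degenerate, ] <- 0
        r[, degenerate] <- 0
        diag(r) <- 1
        r
    }
    r <- solveR()
    for (it in seq_len(exclusionIters)) {
        cand <- abs(r) * incl
        mx <- max(cand)
        if (mx <= exclusionThreshold) break
        hit <- which(cand == mx, arr.ind = TRUE)[1, ]
        incl[hit[1], hit[2]] <- incl[hit[2], hit[1]] <- FALSE
        r <- solveR()
    }
    r
}

## Dirichlet-posterior fractions (prior +1 pseudocount) for one resample,
## or the posterior-mean point estimate when resampling is off.
dirichletFractions <- function(cnt, sample = TRUE) {
    if (!sample)
        return(sweep(cnt + 1, 2, colSums(cnt + 1), "/"))
    g <- matrix(stats::rgamma(length(cnt), shape = cnt + 1),
                nrow(cnt), ncol(cnt))
    sweep(g, 2, colSums(g), "/")
}

#' SparCC compositional correlation estimation
#'
#' Estimates basis (absolute-abundance) correlations between taxa from
#' compositional counts: per Dirichlet resample (prior +1 pseudocount) the
#' log-ratio variation matrix is formed, basis variances are solved under
#' sparsity, pairs stronger than \code{exclusionThreshold} are iteratively
#' excluded and the system re-solved, and the final correlation matrix is
#' the element-wise median over resamples. These are the method's canonical
#' defaults (20 resamples, 10 exclusion rounds, threshold 0.8).
#'
#' @param x an \linkS4class{OtuExperiment} or a taxa x samples count
#'   matrix; needs >= 4 taxa (the basis-variance system is otherwise
#'   unidentifiable) and >= 10 samples.
#' @param nResamples Dirichlet resamples; 0 uses the posterior-mean
#'   fractions once (point estimate, no resampling noise).
#' @param exclusionIters,exclusionThreshold strong-pair exclusion settings.
#' @param seed integer seed.
#' @return a \linkS4class{SparccFit} (p/q filled by
#'   \code{\link{sparccPvalues}}).
#' @references Friedman & Alm (2012) PLoS Comput Biol 8:e1002687.
#' @export
sparcc <- function(x, nResamples = 20, exclusionIters = 10,
                   exclusionThreshold = 0.8, seed) {
    cnt <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    if (nrow(cnt) < 4)
        stop("SparCC needs >= 4 taxa: the basis variance system is ",
             "unidentifiable below that")
    if (ncol(cnt) < 10) stop("SparCC needs >= 10 samples")
    set.seed(childSeed(seed, "sparcc"))
    if (nResamples < 1) {
        r <- sparccCore(dirichletFractions(cnt, sample = FALSE),
                        exclusionIters, exclusionThreshold)
        nRes <- 0L
    } else {
        acc <- array(NA_real_, c(nrow(cnt), nrow(cnt), nResamples))
        for (b in seq_len(nResamples))
            acc[, , b] <- sparccCore(dirichletFractions(cnt),
                                     exclusionIters, exclusionThreshold)
        r <- apply(acc, c(1, 2), stats::median)
        nRes <- as.integer(nResamples)
    }
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(rownames(cnt), rownames(cnt))
    na <- matrix(NA_real_, nrow(cnt), nrow(cnt), dimnames = dimnames(r))
    new("SparccFit", r = r, p = na, q = na, nResamples = nRes,
        nPermutations = 0L)
}

#' Permutation significance for SparCC correlations
#'
#' Builds the null by independently shuffling each taxon's counts across
#' samples (destroying associations while keeping marginal abundance
#' distributions) and re-running the SparCC point estimate. Two-sided
#' p-values are \code{(#\{|r_null| >= |r_obs|\} + 1) / (N + 1)}; by default
#' the null values are pooled across all taxon pairs (exchangeable under
#' this null), which gives p-value resolution fine enough for
#' Benjamini-Hochberg control over tens of thousands of pairs at 100
#' permutations. BH adjustment is applied over the upper triangle.
#'
#' @param x counts used for \code{fit} (\linkS4class{OtuExperiment} or
#'   matrix).
#' @param fit the observed \linkS4class{SparccFit}.
#' @param nPermutations >= 100.
#' @param seed integer seed.
#' @param pool pool null correlations across pairs (default TRUE); with
#'   \code{FALSE} each pair is compared only against its own
#'   \code{nPermutations} null values.
#' @param exclusionIters,exclusionThreshold passed to the null re-fits.
#' @return \code{fit} with p and q matrices filled.
#' @export
sparccPvalues <- function(x, fit, nPermutations = 100, seed, pool = TRUE,
                          exclusionIters = 10, exclusionThreshold = 0.8) {
    if (nPermutations < 100) stop("nPermutations must be >= 100")
    cnt <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    p <- nrow(cnt)
    if (!identical(dim(fit@r), c(p, p)))
        stop("fit does not match the count matrix")
    set.seed(childSeed(seed, "sparcc-null"))
    ut <- upper.tri(fit@r)
    obs <- abs(fit@r[ut])
    if (pool) {
        nullPool <- vector("list", nPermutations)
        for (b in seq_len(nPermutations)) {
            perm <- t(apply(cnt, 1, sample))
            rn <- sparccCore(dirichletFractions(perm, sample = FALSE),
                             exclusionIters, exclusionThreshold)
            nullPool[[b]] <- abs(rn[ut])
        }
        nullAll <- sort(unlist(nullPool))
        ge <- countGE(obs, nullAll)
        pv <- (ge + 1) / (length(nullAll) + 1)
    } else {
        ge <- numeric(length(obs))
        for (b in seq_len(nPermutations)) {
            perm <- t(apply(cnt, 1, sample))
            rn <- sparccCore(dirichletFractions(perm, sample = FALSE),
                             exclusionIters, exclusionThreshold)
            ge <- ge + (abs(rn[ut]) >= obs)
        }
        pv <- (ge + 1) / (nPermutations + 1)
    }
    P <- matrix(NA_real_, p, p, dimnames = dimnames(fit@r))
    Q <- P
    P[ut] <- pv
    Q[ut] <- stats::p.adjust(pv, method = "BH")
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
    fit@p <- P
    fit@q <- Q
    fit@nPermutations <- as.integer(nPermutations)
    fit
}
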