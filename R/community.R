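#' Alpha diversity indices
#'
#' Per-sample observed richness (Sobs), Shannon-Wiener (natural log by
#' default), Simpson (1 - sum p^2), Chao1
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} and ACE (rare cut-off 10), the
#' last two via \code{vegan::estimateR} and therefore requiring integer
#' counts.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param logBase base for Shannon (\code{exp(1)} or 2).
#' @return data.frame (sample, sobs, shannon, simpson, chao1, ace)
#' @export
alphaDiversity <- function(x, logBase = exp(1)) {
    cnt <- t(otuCounts(x))        # samples x taxa for vegan
    if (any(rowSums(cnt) == 0)) stop("empty sample")
    est <- t(vegan::estimateR(round(cnt)))
    data.frame(
        sample = colnames(otuCounts(x)),
        sobs = as.integer(est[, "S.obs"]),
        shannon = vegan::diversity(cnt, index = "shannon", base = logBase),
        simpson = vegan::diversity(cnt, index = "simpson"),
        chao1 = est[, "S.chao1"],
        ace = est[, "S.ACE"],
        row.names = NULL)
}

#' Beta diversity distance matrix
#'
#' Bray-Curtis on proportions, or unweighted/weighted UniFrac on a rooted
#' tree covering all taxa (weighted UniFrac is the normalized variant,
#' bounded in [0, 1], computed through \pkg{phyloseq}).
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param metric one of \code{"bray"}, \code{"unweighted-unifrac"},
#'   \code{"weighted-unifrac"}.
#' @param tree newick text or an \code{ape::phylo} object (UniFrac only).
#' @return a \code{dist} over samples with attribute \code{metric}.
#' @export
betaDistance <- function(x, metric = c("bray", "unweighted-unifrac",
                                       "weighted-unifrac"), tree = NULL) {
    metric <- match.arg(metric)
    if (metric == "bray") {
        prop <- t(relativeAbundance(x))
        d <- vegan::vegdist(prop, method = "bray")
    } else {
        if (is.null(tree)) stop("UniFrac metrics require a tree")
        if (is.character(tree)) tree <- ape::read.tree(text = tree)
        missing <- setdiff(rownames(x), tree$tip.label)
        if (length(missing))
            stop("taxa missing from tree: ",
                 paste(missing, collapse = ", "))
        ps <- phyloseq::phyloseq(
            phyloseq::otu_table(otuCounts(x), taxa_are_rows = TRUE),
            phyloseq::phy_tree(ape::keep.tip(tree, rownames(x))))
        d <- phyloseq::UniFrac(ps,
                               weighted = metric == "weighted-unifrac",
                               normalized = TRUE)
    }
    attr(d, "metric") <- metric
    d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of \eqn{-D^2/2} followed by
#' eigendecomposition; axes are sorted by eigenvalue, negative eigenvalues
#' are reported (not dropped), and per-axis variance fractions use the sum
#' of positive eigenvalues.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @return list: \code{coordinates} (samples x axes, positive-eigenvalue
#'   axes), \code{eigenvalues} (all, sorted), \code{varianceExplained}.
#' @export
pcoaOrdination <- function(d) {
    D <- as.matrix(d)
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
    n <- nrow(D)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    ev <- eg$values
    pos <- ev > 1e-10
    coords <- eg$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(ev[pos]), sum(pos))
    rownames(coords) <- rownames(D)
    if (ncol(coords))
        colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
    ve <- ifelse(ev > 0, ev / sum(ev[ev > 0]), 0)
    list(coordinates = coords, eigenvalues = ev, varianceExplained = ve)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between- versus within-group distances:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = n(n-1)/2};
#' the permutation p-value uses the \eqn{(hits + 1)/(n_{perm} + 1)}
#' estimator. Delegates to \code{vegan::anosim} under a fixed seed.
#'
#' @param d a \code{dist} over samples.
#' @param groups group labels (>= 2 groups of >= 2 samples each).
#' @param nPerm number of permutations, default 999.
#' @param seed integer seed.
#' @return list (R, p, nPerm)
#' @export
anosimTest <- function(d, groups, nPerm = 999, seed) {
    groups <- as.factor(groups)
    if (nlevels(groups) < 2 || any(table(groups) < 2))
        stop("need >= 2 groups with >= 2 samples each")
    set.seed(childSeed(seed, "anosim"))
    ## vegan chats when it switches to complete enumeration
    an <- suppressMessages(vegan::anosim(d, groups,
                                         permutations = nPerm))
    list(R = unname(an$statistic), p = an$signif, nPerm = nPerm)
}

#' Two-group rank-sum tests with BH adjustment
#'
#' Two-sided Wilcoxon rank-sum test per feature (normal approximation
#' with tie correction), BH adjustment across all features of the matrix
#' (one feature family per call). Constant features get p = 1 and are
#' flagged.
#'
#' @param features features x samples matrix (e.g. proportions from
#'   \code{\link{relativeAbundance}}).
#' @param groups two-level labels aligned with columns.
#' @return data.frame (feature, medianA, medianB, W, p, q, constant);
#'   A = first group level.
#' @export
groupDifferenceTest <- function(features, groups) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("exactly two groups required")
    gA <- levels(groups)[1]
    res <- lapply(seq_len(nrow(features)), function(i) {
        v <- features[i, ]
        a <- v[groups == gA]
        b <- v[groups != gA]
        if (stats::sd(v) == 0)
            return(data.frame(feature = rownames(features)[i],
                              medianA = stats::median(a),
                              medianB = stats::median(b),
                              W = NA_real_, p = 1, constant = TRUE))
        wt <- suppressWarnings(
            stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
        data.frame(feature = rownames(features)[i],
                   medianA = stats::median(a), medianB = stats::median(b),
                   W = unname(wt$statistic), p = wt$p.value,
                   constant = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out[, c("feature", "medianA", "medianB", "W", "p", "q", "constant")]
}

#' Spearman correlations between genus abundance and blood metals
#'
#' Tie-aware Spearman rho per (genus, metal) pair over the samples with a
#' measurement, with BH adjustment across the whole genus x metal grid.
#' All-tied metal vectors give an undefined rho, reported as NA.
#'
#' @param genusAbundance genera x samples proportion matrix (e.g.
#'   \code{relativeAbundance(x, "genus")}).
#' @param x an \linkS4class{OtuExperiment} with metal columns, or a
#'   samples x metals matrix. At least 10 samples must carry measurements.
#' @return data.frame (genus, metal, n, rho, p, q)
#' @export
spearmanMetalCorrelation <- function(genusAbundance, x) {
    metals <- if (is(x, "OtuExperiment")) metalConcentrations(x) else
        as.matrix(x)
    if (is.null(metals)) stop("no metal concentrations available")
    common <- intersect(colnames(genusAbundance), rownames(metals))
    out <- list()
    for (g in rownames(genusAbundance)) for (met in colnames(metals)) {
        ok <- common[!is.na(metals[common, met])]
        if (length(ok) < 10)
            stop("need >= 10 samples with metal measurements")
        mv <- metals[ok, met]
        gv <- genusAbundance[g, ok]
        if (stats::sd(mv) == 0 || stats::sd(gv) == 0) {
            out[[length(out) + 1]] <- data.frame(
                genus = g, metal = met, n = length(ok),
                rho = NA_real_, p = NA_real_)
            next
        }
        ct <- suppressWarnings(
            stats::cor.test(gv, mv, method = "spearman", exact = FALSE))
        out[[length(out) + 1]] <- data.frame(
            genus = g, metal = met, n = length(ok),
            rho = unname(ct$estimate), p = ct$p.value)
    }
    res <- do.call(rbind, out)
    res$q <- NA_real_
    res$q[!is.na(res$p)] <- stats::p.adjust(res$p[!is.na(res$p)],
                                            method = "BH")
    res
}
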