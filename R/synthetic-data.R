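#' Plant a modular basis correlation structure
#'
#' Builds the ground-truth model behind a synthetic study: taxa are split
#' evenly into \code{nModules} blocks; within each block a one-factor
#' loading construction places pairwise log-scale correlations of magnitude
#' \code{rhoRange} between loaded taxa, with a \code{negativeFraction} of
#' planted pairs negative (taxa on opposite factor poles). The off-block
#' correlation is exactly 0. With \code{intraDensity < 1} a random subset of
#' within-block pairs is planted and the matrix is repaired to the nearest
#' positive-semidefinite correlation matrix (\code{Matrix::nearPD}); if the
#' repair degrades or sign-flips a planted correlation the call fails rather
#' than silently clipping.
#'
#' @param nTaxa total taxa (>= 4 * nModules).
#' @param nModules number of planted modules.
#' @param intraDensity fraction of within-module pairs planted (1 = all).
#' @param negativeFraction target fraction of planted pairs with negative
#'   correlation; must be <= 0.5 for a one-factor block (denser negative
#'   structure is not positive semidefinite).
#' @param seed integer master seed.
#' @param rhoRange range of |correlation| planted within modules.
#' @param backgroundFraction fraction of taxa left unassigned (module id 0,
#'   mutually independent) to emulate the unstructured bulk of an OTU table.
#' @param nSamplesPerGroup named integer vector,
#'   \code{c(exposure =, control =)}; the study design emulated here
#'   enrolled 92 exposed and 45 control subjects.
#' @param groupEffects optional named numeric vector of natural-log fold
#'   changes (exposure minus control) for a subset of taxa.
#' @param metalLoadings optional data.frame with columns \code{metal},
#'   \code{module}, \code{coefficient}, \code{noiseSd} describing linear
#'   couplings between blood-metal concentrations and module abundance.
#' @return a \linkS4class{PlantedModel}
#' @examples
#' pm <- plantNetwork(20, 4, intraDensity = 1, negativeFraction = 0.1,
#'                    seed = 1)
#' @export
plantNetwork <- function(nTaxa, nModules, intraDensity = 1,
                         negativeFraction = 0.1, seed,
                         rhoRange = c(0.65, 0.85),
                         backgroundFraction = 0,
                         nSamplesPerGroup = c(exposure = 92L, control = 45L),
                         groupEffects = NULL, metalLoadings = NULL) {
    if (nModules >= 1 && nTaxa < 4 * nModules)
        stop("need nTaxa >= 4 * nModules")
    if (intraDensity < 0 || intraDensity > 1 ||
        negativeFraction < 0 || negativeFraction > 1)
        stop("fractions must lie in [0, 1]")
    if (negativeFraction > 0.5 && intraDensity > 0)
        stop("negative correlations too dense: a fraction above 0.5 of ",
             "negative planted pairs is not positive semidefinite ",
             "representable by this generator")
    set.seed(childSeed(seed, "plant"))
    taxa <- sprintf("OTU%04d", seq_len(nTaxa))
    nBack <- round(backgroundFraction * nTaxa)
    nLoaded <- nTaxa - nBack
    mod <- integer(nTaxa)
    mod[seq_len(nLoaded)] <- rep_len(seq_len(max(nModules, 1L)), nLoaded)
    C <- diag(nTaxa)
    edges <- list()
    ## fraction q of negative loadings gives negative-pair fraction
    ## 2 q (1 - q) within a block
    q <- if (negativeFraction > 0) (1 - sqrt(1 - 2 * negativeFraction)) / 2
         else 0
    for (m in seq_len(nModules)) {
        idx <- which(mod == m)
        sz <- length(idx)
        if (sz < 2 || intraDensity == 0) next
        u <- stats::runif(sz, rhoRange[1], rhoRange[2])
        s <- ifelse(stats::runif(sz) < q, -1, 1)
        load <- s * sqrt(u)
        B <- outer(load, load)
        diag(B) <- 1
        pairs <- upperPairs(sz)
        if (intraDensity < 1) {
            keep <- stats::runif(nrow(pairs)) < intraDensity
            dropP <- pairs[!keep, , drop = FALSE]
            B[cbind(dropP[, 1], dropP[, 2])] <- 0
            B[cbind(dropP[, 2], dropP[, 1])] <- 0
            pairs <- pairs[keep, , drop = FALSE]
        }
        C[idx, idx] <- B
        if (nrow(pairs))
            edges[[m]] <- data.frame(i = idx[pairs[, 1]],
                                     j = idx[pairs[, 2]],
                                     rho = B[cbind(pairs[, 1], pairs[, 2])])
    }
    edgeTruth <- if (length(edges)) do.call(rbind, edges) else
        data.frame(i = integer(), j = integer(), rho = numeric())
    minEig <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (minEig < -1e-8) {
        rep <- Matrix::nearPD(C, corr = TRUE, maxit = 200)
        C2 <- as.matrix(rep$mat)
        ## keep the off-block entries exactly zero: the block-diagonal
        ## projection of a PSD matrix is still PSD
        sameBlock <- outer(mod, mod, "==") & outer(mod, mod, "*") > 0
        C2[!sameBlock & row(C2) != col(C2)] <- 0
        if (nrow(edgeTruth)) {
            old <- edgeTruth$rho
            newv <- C2[cbind(edgeTruth$i, edgeTruth$j)]
            if (any(sign(newv) != sign(old)) || any(abs(newv) < 0.45))
                stop("planted structure not representable: PSD repair ",
                     "degraded planted correlations below 0.45 or flipped ",
                     "their sign; reduce intraDensity or negativeFraction")
            edgeTruth$rho <- newv
        }
        C <- C2
    }
    rownames(C) <- colnames(C) <- taxa
    ge <- stats::setNames(numeric(nTaxa), taxa)
    if (!is.null(groupEffects)) {
        bad <- setdiff(names(groupEffects), taxa)
        if (length(bad)) stop("unknown taxa in groupEffects: ",
                              paste(bad, collapse = ", "))
        ge[names(groupEffects)] <- groupEffects
    }
    ml <- if (is.null(metalLoadings))
        data.frame(metal = character(), module = integer(),
                   coefficient = numeric(), noiseSd = numeric())
    else as.data.frame(metalLoadings)
    if (nrow(ml) && !all(ml$module %in% mod[mod > 0]))
        stop("metalLoadings reference modules that were not planted")
    ## Background taxa follow a broad lognormal rank-abundance curve;
    ## module taxa are drawn from a moderately abundant stratum, since a
    ## co-occurrence network is by construction built over detectable taxa
    ## (correlations of taxa near the detection limit are not recoverable
    ## from counts).
    lm0 <- stats::rnorm(nTaxa, 0, 1.5)
    lm0[mod > 0] <- stats::rnorm(sum(mod > 0), 1.5, 1.0)
    new("PlantedModel",
        taxonIds = taxa,
        moduleAssignment = as.integer(mod),
        basisCorrelation = C,
        logMean = lm0,
        logSd = stats::runif(nTaxa, 0.6, 1.2),
        edgeTruth = edgeTruth,
        groupEffects = ge,
        metalLoadings = ml,
        nSamplesPerGroup = stats::setNames(as.integer(nSamplesPerGroup),
                                           names(nSamplesPerGroup)),
        seed = as.integer(seed))
}

#' Simulate an OTU count table from a planted model
#'
#' For each sample, log basis abundances are drawn from the multivariate
#' normal defined by the model (group log-fold-changes added to exposure
#' means), closed to proportions, and counts drawn multinomially at the
#' requested depth, the standard compositional log-normal/multinomial model
#' under which the SparCC estimand (basis correlation) is well defined.
#' Every sample's counts sum to exactly \code{depth}.
#'
#' @param model a \linkS4class{PlantedModel}
#' @param depth reads per sample (>= 100); the study emulated here was
#'   rarefied to 28,367 reads per sample.
#' @param seed integer seed.
#' @return an \linkS4class{OtuExperiment} with group labels in colData.
#' @export
simulateCounts <- function(model, depth = 28367, seed) {
    if (depth < 100) stop("depth must be >= 100")
    p <- length(model@taxonIds)
    Sigma <- diag(model@logSd) %*% model@basisCorrelation %*%
        diag(model@logSd)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(!is.finite(ev)))
        stop("degenerate covariance: non-finite eigenvalues")
    nPer <- model@nSamplesPerGroup
    grp <- rep(names(nPer), nPer)
    n <- sum(nPer)
    set.seed(childSeed(seed, "counts"))
    Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
    Z <- sweep(Z, 2, model@logMean, "+")
    isExp <- grp == "exposure"
    Z[isExp, ] <- sweep(Z[isExp, , drop = FALSE], 2, model@groupEffects,
                        "+")
    cnt <- matrix(0, p, n,
                  dimnames = list(model@taxonIds,
                                  sprintf("S%03d", seq_len(n))))
    for (s in seq_len(n)) {
        w <- exp(Z[s, ] - max(Z[s, ]))
        cnt[, s] <- stats::rmultinom(1, depth, w / sum(w))
    }
    OtuExperiment(cnt, taxonomy = syntheticLineages(model),
                  group = grp)
}

## Deterministic synthetic lineages: each planted module is drawn from one
## phylum (as real co-occurrence modules tend to be taxonomically coherent);
## background taxa get phyla at random. Derived from the model seed only.
syntheticLineages <- function(model) {
    phyla <- c("Firmicutes", "Actinobacteriota", "Proteobacteria",
               "Fusobacteriota", "Bacteroidota", "Patescibacteria",
               "Spirochaetota", "Synergistota")
    set.seed(childSeed(model@seed, "lineage"))
    mod <- model@moduleAssignment
    ph <- character(length(mod))
    modPhyla <- sample(phyla, max(mod, 1), replace = TRUE)
    ph[mod > 0] <- modPhyla[mod[mod > 0]]
    ph[mod == 0] <- sample(phyla, sum(mod == 0), replace = TRUE)
    sprintf("k__Bacteria;p__%s;c__;o__;f__;g__Genus%03d;s__",
            ph, seq_along(mod))
}

#' Simulate per-sample metadata (group labels and blood metals)
#'
#' Each metal in the model's loadings equals
#' \code{coefficient * (mean standardized relative abundance of the
#' module's taxa in the sample) + Gaussian noise}, shifted by a constant
#' baseline so concentrations stay non-negative. Metals named in
#' \code{extraMetals} are pure noise (no module coupling). Group labels are
#' copied from the model through the table.
#'
#' @param model a \linkS4class{PlantedModel}
#' @param table the \linkS4class{OtuExperiment} the metals should reflect.
#' @param seed integer seed.
#' @param baseline additive constant (ug/L) keeping concentrations
#'   positive.
#' @param extraMetals character vector of uncoupled metals to include.
#' @param nMeasured optionally restrict metal measurements to this many
#'   samples (the rest get NA), emulating a blood subset.
#' @return the table with metals attached to colData.
#' @export
simulateMetadata <- function(model, table, seed, baseline = 10,
                             extraMetals = character(), nMeasured = NULL) {
    ml <- model@metalLoadings
    if (nrow(ml) && !all(ml$module %in% model@moduleAssignment))
        stop("metalLoadings reference non-existent modules")
    prop <- relativeAbundance(table)
    n <- ncol(prop)
    set.seed(childSeed(seed, "metadata"))
    metals <- list()
    for (k in seq_len(nrow(ml))) {
        taxa <- model@taxonIds[model@moduleAssignment == ml$module[k]]
        taxa <- intersect(taxa, rownames(prop))
        z <- scale(t(prop[taxa, , drop = FALSE]))  # samples x taxa
        score <- rowMeans(z)
        metals[[ml$metal[k]]] <- pmax(
            0, baseline + ml$coefficient[k] * score +
               stats::rnorm(n, 0, ml$noiseSd[k]))
    }
    for (m in extraMetals)
        metals[[m]] <- pmax(0, baseline + stats::rnorm(n))
    if (!length(metals)) return(table)
    md <- do.call(cbind, metals)
    rownames(md) <- colnames(prop)
    if (!is.null(nMeasured) && nMeasured < n) {
        unmeasured <- sample(n, n - nMeasured)
        md[unmeasured, ] <- NA
    }
    cd <- SummarizedExperiment::colData(table)
    for (cl in colnames(md)) cd[[cl]] <- md[, cl]
    SummarizedExperiment::colData(table) <- cd
    table
}

#' Simulate a random rooted bifurcating tree over taxa
#'
#' @param taxa character vector of (unique) taxon ids, length >= 2.
#' @param seed integer seed; identical seeds give byte-identical newick.
#' @return newick text (rooted, bifurcating, strictly positive branch
#'   lengths).
#' @export
simulateTree <- function(taxa, seed) {
    if (anyDuplicated(taxa)) stop("duplicate taxon ids")
    if (length(taxa) < 2) stop("need at least 2 taxa")
    set.seed(childSeed(seed, "tree"))
    tr <- ape::rtree(length(taxa), rooted = TRUE, tip.label = taxa,
                     br = function(n) stats::runif(n, 0.05, 1))
    ape::write.tree(tr)
}

#' Write the planted ground truth as JSON
#'
#' @param model a \linkS4class{PlantedModel}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGroundTruth <- function(model, path) {
    obj <- list(
        taxa = model@taxonIds,
        module = stats::setNames(model@moduleAssignment, model@taxonIds),
        edges = model@edgeTruth,
        groupEffects = model@groupEffects[model@groupEffects != 0],
        metalLoadings = model@metalLoadings,
        nSamplesPerGroup = as.list(model@nSamplesPerGroup),
        seed = model@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
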