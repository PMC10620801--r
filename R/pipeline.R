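#' Pipeline configuration
#'
#' Assembles and validates the settings of an end-to-end run. Defaults
#' follow the study design this pipeline reproduces: occupancy filter at
#' 0.10 applied per group after shared rarefaction, SparCC with 20
#' Dirichlet resamples / 10 exclusion iterations / exclusion threshold
#' 0.8, 100 pooled permutations, RMT grid 0.30-0.95 step 0.01 (or a
#' pinned cut-off), q < 0.05, and 100-network null ensembles.
#'
#' @param otuTable path to an OTU TSV, or an \linkS4class{OtuExperiment}.
#' @param metadata path to a metadata TSV, or NULL when the table already
#'   carries colData.
#' @param tree newick path/text or NULL (beta diversity falls back to
#'   Bray-Curtis).
#' @param syntheticModel a \linkS4class{PlantedModel} to simulate from
#'   instead of reading inputs.
#' @param depth rarefaction depth or \code{"min"}.
#' @param prevalenceFraction occupancy threshold, default 0.10.
#' @param prevalenceScope \code{"per-group"} (default) or
#'   \code{"global"}.
#' @param sparccResamples,sparccExclusionIters,sparccExclusionThreshold
#'   SparCC settings.
#' @param nPermutations permutation count for significance.
#' @param rmtGrid candidate cut-offs; ignored when \code{pinnedCutoff}
#'   is set.
#' @param pinnedCutoff fix the cut-off (e.g. 0.45) instead of scanning.
#' @param qMax FDR threshold, default 0.05.
#' @param ensembleSize Maslov-Sneppen ensemble size, default 100.
#' @param removeIndirect reserved flag for indirect-edge removal; the
#'   stage is not implemented and is logged as skipped when TRUE.
#' @param eigengeneNetwork build the third (metal-subset) network for the
#'   eigengene stage, default TRUE when metals are present.
#' @param simulateDepth depth for synthetic count simulation.
#' @param seed master seed.
#' @param outDir output directory.
#' @return a validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(otuTable = NULL, metadata = NULL, tree = NULL,
                           syntheticModel = NULL, depth = "min",
                           prevalenceFraction = 0.10,
                           prevalenceScope = c("per-group", "global"),
                           sparccResamples = 20,
                           sparccExclusionIters = 10,
                           sparccExclusionThreshold = 0.8,
                           nPermutations = 100,
                           rmtGrid = seq(0.30, 0.95, by = 0.01),
                           pinnedCutoff = NULL, qMax = 0.05,
                           ensembleSize = 100, removeIndirect = FALSE,
                           eigengeneNetwork = TRUE,
                           simulateDepth = 28367, seed = 1,
                           outDir = tempfile("menrun")) {
    if (is.null(otuTable) && is.null(syntheticModel))
        stop("either otuTable or syntheticModel is required")
    cfg <- list(otuTable = otuTable, metadata = metadata, tree = tree,
                syntheticModel = syntheticModel, depth = depth,
                prevalenceFraction = prevalenceFraction,
                prevalenceScope = match.arg(prevalenceScope),
                sparccResamples = sparccResamples,
                sparccExclusionIters = sparccExclusionIters,
                sparccExclusionThreshold = sparccExclusionThreshold,
                nPermutations = nPermutations, rmtGrid = rmtGrid,
                pinnedCutoff = pinnedCutoff, qMax = qMax,
                ensembleSize = ensembleSize,
                removeIndirect = isTRUE(removeIndirect),
                eigengeneNetwork = isTRUE(eigengeneNetwork),
                simulateDepth = simulateDepth,
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror \code{\link{pipelineConfig}}
#'   arguments.
#' @return a \code{pipelineConfig}
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

logMsg <- function(con, ...) {
    txt <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
    message(txt)
    if (!is.null(con)) writeLines(txt, con)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

groupNetworkStage <- function(x, label, cfg, log) {
    logMsg(log, "[network:", label, "] ", ncol(x), " samples")
    xf <- prevalenceFilter(x, cfg$prevalenceFraction)
    logMsg(log, "[network:", label, "] ", nrow(xf),
           " OTUs pass the occupancy filter")
    if (cfg$removeIndirect)
        logMsg(log, "[network:", label,
               "] indirect-edge removal requested but not implemented; ",
               "stage skipped")
    fit <- sparcc(xf, nResamples = cfg$sparccResamples,
                  exclusionIters = cfg$sparccExclusionIters,
                  exclusionThreshold = cfg$sparccExclusionThreshold,
                  seed = childSeed(cfg$seed, paste0("sparcc-", label)))
    fit <- sparccPvalues(xf, fit, nPermutations = cfg$nPermutations,
                         seed = childSeed(cfg$seed, paste0("perm-", label)),
                         exclusionIters = cfg$sparccExclusionIters,
                         exclusionThreshold = cfg$sparccExclusionThreshold)
    scan <- if (!is.null(cfg$pinnedCutoff)) pinCutoff(cfg$pinnedCutoff)
            else rmtSelectCutoff(fit, grid = cfg$rmtGrid)
    logMsg(log, "[network:", label, "] cut-off s_t = ", scan@selected)
    net <- buildNetwork(fit, scan, qMax = cfg$qMax,
                        taxonomy = taxonomy(xf))
    part <- greedyModularity(net)
    topo <- topologyIndices(net, part)
    ens <- nullEnsemble(net, k = cfg$ensembleSize,
                        seed = childSeed(cfg$seed, paste0("null-", label)))
    roles <- ziPi(net, part)
    d <- cfg$outDir
    writeNetwork(net, d, paste0(label, "_network"))
    writeTopology(ens, file.path(d, paste0(label, "_topology.tsv")))
    writeTsv(roles, file.path(d, paste0(label, "_roles.tsv")))
    list(network = net, partition = part, topology = topo,
         nullComparison = ens, roles = roles, cutoff = scan@selected,
         signs = edgeSignSummary(net))
}

#' Run the full analysis pipeline
#'
#' preprocess -> diversity/ordination/group tests -> per-group SparCC +
#' RMT network -> topology with null ensemble -> modules, Zi-Pi roles ->
#' eigengene-metal correlations. Every stage's tables are written under
#' \code{config$outDir} together with a JSON manifest; log lines go to
#' stderr and \code{pipeline.log}. The manifest contains no wall-clock
#' state, so identical seeds give byte-identical manifests.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    log <- file(file.path(config$outDir, "pipeline.log"), "w")
    on.exit(close(log))
    stage <- "input"
    manifest <- list(package = "microMEN",
                     version = as.character(utils::packageVersion(
                         "microMEN")),
                     seed = config$seed,
                     config = configFingerprint(config),
                     stages = list())
    result <- tryCatch({
        ## ---- input ----
        if (!is.null(config$syntheticModel)) {
            logMsg(log, "[input] simulating from planted model")
            x <- simulateCounts(config$syntheticModel,
                                depth = config$simulateDepth,
                                seed = childSeed(config$seed, "sim"))
            x <- simulateMetadata(config$syntheticModel, x,
                                  seed = childSeed(config$seed, "simmd"))
            treeText <- simulateTree(rownames(x),
                                     seed = childSeed(config$seed,
                                                      "simtree"))
            writeOtuTable(x, file.path(config$outDir, "otu_table.tsv"))
            writeSampleMetadata(x, file.path(config$outDir,
                                             "metadata.tsv"))
            writeLines(treeText, file.path(config$outDir, "tree.nwk"))
            writeGroundTruth(config$syntheticModel,
                             file.path(config$outDir,
                                       "ground_truth.json"))
        } else {
            x <- if (is(config$otuTable, "OtuExperiment"))
                config$otuTable else readOtuTable(config$otuTable)
            if (!is.null(config$metadata)) {
                if (!is.character(config$metadata))
                    stop("metadata must be a file path")
                x <- attachSampleMetadata(
                    x, readSampleMetadata(config$metadata))
            }
            treeText <- NULL
            if (!is.null(config$tree))
                treeText <- if (file.exists(config$tree))
                    paste(readLines(config$tree), collapse = "") else
                    config$tree
        }
        if (is.null(sampleGroups(x)))
            stop("no group labels: metadata with a 'group' column is ",
                 "required")
        grp <- sampleGroups(x)
        manifest$stages$input <- list(
            taxa = nrow(x), samples = ncol(x),
            groups = as.list(table(grp)))

        ## ---- preprocess ----
        stage <- "preprocess"
        x <- rarefyCounts(x, depth = config$depth,
                          seed = childSeed(config$seed, "rarefy"))
        depthUsed <- unique(colSums(otuCounts(x)))[1]
        logMsg(log, "[preprocess] rarefied to ", depthUsed,
               " reads/sample; ", nrow(x), " taxa remain")
        manifest$stages$preprocess <- list(depth = depthUsed,
                                           taxa = nrow(x))

        ## ---- community analysis ----
        stage <- "community"
        grp <- sampleGroups(x)
        alpha <- alphaDiversity(x)
        writeTsv(alpha, file.path(config$outDir, "alpha_diversity.tsv"))
        alphaTests <- lapply(
            c("sobs", "shannon", "simpson", "chao1", "ace"),
            function(ix) {
                wt <- stats::wilcox.test(alpha[[ix]][grp == "exposure"],
                                         alpha[[ix]][grp == "control"],
                                         exact = FALSE)
                data.frame(index = ix, p = wt$p.value)
            })
        writeTsv(do.call(rbind, alphaTests),
                 file.path(config$outDir, "alpha_tests.tsv"))
        metric <- if (!is.null(treeText)) "weighted-unifrac" else "bray"
        d <- betaDistance(x, metric = metric, tree = treeText)
        utils::write.table(as.matrix(d),
                           file.path(config$outDir, "beta_distance.tsv"),
                           sep = "\t", quote = FALSE)
        ord <- pcoaOrdination(d)
        writeTsv(data.frame(sample = rownames(ord$coordinates),
                            ord$coordinates[, seq_len(
                                min(4, ncol(ord$coordinates))),
                                drop = FALSE]),
                 file.path(config$outDir, "pcoa.tsv"))
        an <- anosimTest(d, grp, seed = childSeed(config$seed, "anosim"))
        phylumTests <- groupDifferenceTest(
            relativeAbundance(x, "phylum"), grp)
        genusProp <- relativeAbundance(x, "genus")
        genusTests <- groupDifferenceTest(genusProp, grp)
        writeTsv(phylumTests, file.path(config$outDir,
                                        "phylum_tests.tsv"))
        writeTsv(genusTests, file.path(config$outDir, "genus_tests.tsv"))
        metals <- metalConcentrations(x)
        metalCors <- NULL
        if (!is.null(metals)) {
            metalCors <- spearmanMetalCorrelation(genusProp, x)
            writeTsv(metalCors, file.path(config$outDir,
                                          "genus_metal_spearman.tsv"))
        }
        manifest$stages$community <- list(
            betaMetric = metric,
            anosim = list(R = an$R, p = an$p),
            pcoaVariance = as.list(round(
                ord$varianceExplained[seq_len(
                    min(2, length(ord$varianceExplained)))], 4)))

        ## ---- per-group networks ----
        stage <- "networks"
        nets <- list()
        for (gLab in c("exposure", "control")) {
            xg <- x[, grp == gLab]
            if (config$prevalenceScope == "global")
                xg <- prevalenceFilter(x,
                                       config$prevalenceFraction)[,
                                       grp == gLab]
            nets[[gLab]] <- groupNetworkStage(xg, gLab, config, log)
        }
        comp <- compareNetworks(nets$exposure$network,
                                nets$control$network)
        manifest$stages$networks <- lapply(nets, function(s) list(
            nodes = unname(s$topology["N"]),
            links = unname(s$topology["L"]),
            cutoff = s$cutoff,
            modularity = unname(s$topology["Q"]),
            positivePct = unname(s$signs["positivePct"]),
            modulesGt4 = modulesLargerThan(s$partition),
            keystone = sum(s$roles$role %in% c("module hub",
                                               "connector"))))
        manifest$stages$networks$comparison <- as.list(comp$counts)

        ## ---- eigengene-metal stage ----
        stage <- "eigengenes"
        if (config$eigengeneNetwork && !is.null(metals)) {
            measured <- rownames(metals)[stats::complete.cases(metals)]
            xm <- x[, intersect(colnames(x), measured)]
            em <- groupNetworkStage(xm, "metal_subset", config, log)
            eig <- moduleEigengenes(xm, em$partition)
            emCor <- eigengeneMetalCorrelation(eig, xm)
            writeTsv(emCor, file.path(config$outDir,
                                      "eigengene_metal_pearson.tsv"))
            writeTsv(data.frame(sample = rownames(eigengenes(eig)),
                                eigengenes(eig)),
                     file.path(config$outDir, "eigengenes.tsv"))
            manifest$stages$eigengenes <- list(
                modules = ncol(eigengenes(eig)),
                significantPairs = sum(emCor$p < 0.05))
            nets$metal_subset <- em
        } else {
            logMsg(log, "[eigengenes] no metal data; stage skipped")
        }
        list(manifest = manifest, networks = nets,
             anosim = an, alpha = alpha, x = x,
             genusTests = genusTests, phylumTests = phylumTests,
             metalCors = metalCors)
    }, error = function(e)
        stop("pipeline failed in stage '", stage, "': ",
             conditionMessage(e), call. = FALSE))
    jsonlite::write_json(result$manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logMsg(log, "[done] outputs in ", config$outDir)
    invisible(result)
}

## Config echo for the manifest: drop non-scalar objects, keep settings.
configFingerprint <- function(cfg) {
    keep <- c("depth", "prevalenceFraction", "prevalenceScope",
              "sparccResamples", "sparccExclusionIters",
              "sparccExclusionThreshold", "nPermutations", "pinnedCutoff",
              "qMax", "ensembleSize", "removeIndirect", "simulateDepth",
              "seed")
    out <- cfg[keep]
    out$rmtGrid <- range(cfg$rmtGrid)
    out[!vapply(out, is.null, logical(1))]
}

#' Human-readable report of a pipeline run
#'
#' @param result return value of \code{\link{runPipeline}}.
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly when written.
#' @export
summarizeRun <- function(result, path = NULL) {
    m <- result$manifest
    ln <- c("Molecular ecological network analysis report",
            paste0("  seed: ", m$seed))
    ln <- c(ln, paste0("  samples: ",
                       paste(names(m$stages$input$groups),
                             unlist(m$stages$input$groups),
                             sep = "=", collapse = ", "),
                       "; taxa: ", m$stages$input$taxa))
    cm <- m$stages$community
    ln <- c(ln, paste0("  beta diversity (", cm$betaMetric, "): ANOSIM R = ",
                       round(cm$anosim$R, 3), ", p = ", cm$anosim$p))
    for (gLab in intersect(c("exposure", "control", "metal_subset"),
                           names(result$networks))) {
        s <- result$networks[[gLab]]
        keyst <- s$roles[s$roles$role %in% c("module hub", "connector"), ]
        ln <- c(ln,
                paste0("  [", gLab, "] N=", s$topology[["N"]],
                       " L=", s$topology[["L"]],
                       " avgK=", round(s$topology[["avgK"]], 3),
                       " Q=", round(s$topology[["Q"]], 3),
                       " cutoff=", s$cutoff,
                       " positive%=", round(s$signs[["positivePct"]], 2)))
        ln <- c(ln, if (nrow(keyst) == 0)
            paste0("    no keystone taxa (all nodes peripheral)")
            else paste0("    keystone taxa: ",
                        paste(keyst$node, " (", keyst$role, ")",
                              sep = "", collapse = ", ")))
    }
    if (is.null(result$metalCors))
        ln <- c(ln, "  metal section omitted: no metal concentrations")
    if (!is.null(path)) {
        writeLines(ln, path)
        return(invisible(ln))
    }
    ln
}
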