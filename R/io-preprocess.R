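#' Read an OTU table from TSV
#'
#' Expects a header row of sample ids, a first column of OTU ids, integer
#' counts, and an optional trailing \code{taxonomy} column of
#' semicolon-delimited lineages. Row/column order is preserved.
#'
#' @param path path to a tab-separated file.
#' @return an \linkS4class{OtuExperiment}
#' @seealso \code{\link{writeOtuTable}}
#' @export
readOtuTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", sep = "\t",
                            quote = "")
    if (ncol(df) < 2) stop("need at least one sample column in ", path)
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate OTU ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    taxCol <- tolower(colnames(df)) == "taxonomy"
    tax <- if (any(taxCol)) df[[which(taxCol)[1]]] else NULL
    cntDf <- df[, !taxCol, drop = FALSE][, -1, drop = FALSE]
    if (anyDuplicated(colnames(cntDf)))
        stop("duplicate sample ids in header of ", path)
    cnt <- matrix(NA_real_, nrow(cntDf), ncol(cntDf),
                  dimnames = list(ids, colnames(cntDf)))
    for (j in seq_len(ncol(cntDf))) {
        v <- suppressWarnings(as.numeric(cntDf[[j]]))
        bad <- which(is.na(v) | v != round(v) | v < 0)
        if (length(bad))
            stop("non-integer or negative count in ", path, ", row '",
                 ids[bad[1]], "' (line ", bad[1] + 1L, "), sample '",
                 colnames(cntDf)[j], "': ", cntDf[[j]][bad[1]])
        cnt[, j] <- v
    }
    OtuExperiment(cnt, taxonomy = tax)
}

#' Write an OTU table to TSV
#'
#' Inverse of \code{\link{readOtuTable}}: sample columns followed by a
#' trailing \code{taxonomy} column.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeOtuTable <- function(x, path) {
    cnt <- otuCounts(x)
    df <- data.frame(`#OTU ID` = rownames(cnt), cnt,
                     taxonomy = unname(taxonomy(x)),
                     check.names = FALSE)
    colnames(df)[2:(ncol(cnt) + 1)] <- colnames(cnt)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write per-sample metadata (group label and metal concentrations)
#'
#' TSV with columns \code{sample_id}, \code{group}, then one column per
#' metal (ug/L). \code{attachSampleMetadata} merges the metadata into the
#' \code{colData} of an \linkS4class{OtuExperiment}; metadata sample ids
#' must be a subset of the table's samples.
#'
#' @param path TSV path
#' @return \code{readSampleMetadata}: a data.frame with rownames = sample
#'   ids.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            sep = "\t", quote = "")
    if (!"sample_id" %in% colnames(df))
        stop("metadata must have a sample_id column: ", path)
    rownames(df) <- df$sample_id
    df$sample_id <- NULL
    metals <- setdiff(colnames(df), "group")
    for (m in metals) {
        if (any(df[[m]] < 0, na.rm = TRUE))
            stop("negative concentration for ", m, " in ", path)
    }
    df
}

#' @rdname readSampleMetadata
#' @param x an \linkS4class{OtuExperiment}
#' @param md data.frame from \code{readSampleMetadata}
#' @export
attachSampleMetadata <- function(x, md) {
    extra <- setdiff(rownames(md), colnames(x))
    if (length(extra))
        stop("metadata samples absent from OTU table: ",
             paste(extra, collapse = ", "))
    cd <- SummarizedExperiment::colData(x)
    for (cl in colnames(md))
        cd[[cl]] <- md[match(rownames(cd), rownames(md)), cl]
    SummarizedExperiment::colData(x) <- cd
    validObject(x)
    x
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(x, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    df <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples every sample without replacement (multivariate
#' hypergeometric) to exactly \code{depth} reads; samples shallower than
#' \code{depth} are dropped with a warning, and taxa left with zero total
#' count are removed.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param depth target reads per sample, or \code{"min"} for the smallest
#'   sample total.
#' @param seed integer seed (required: downstream counts depend on it).
#' @return a rarefied \linkS4class{OtuExperiment}
#' @export
rarefyCounts <- function(x, depth = "min", seed) {
    cnt <- otuCounts(x)
    totals <- colSums(cnt)
    if (identical(depth, "min")) depth <- min(totals)
    depth <- as.numeric(depth)
    if (length(depth) != 1 || !is.finite(depth) || depth <= 0)
        stop("depth must be a single positive number")
    drop <- totals < depth
    if (any(drop)) {
        warning(sum(drop), " sample(s) below depth ", depth, " dropped: ",
                paste(colnames(cnt)[drop], collapse = ", "))
        cnt <- cnt[, !drop, drop = FALSE]
        x <- x[, !drop]
    }
    if (!ncol(cnt)) stop("no samples at or above depth ", depth)
    set.seed(childSeed(seed, "rarefy"))
    ## vegan warns on any table whose smallest positive count exceeds 1;
    ## spurious for valid integer counts
    rar <- withCallingHandlers(
        t(vegan::rrarefy(t(cnt), depth)),
        warning = function(w) {
            if (grepl("observed counts", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    keep <- rowSums(rar) > 0
    out <- x[keep, ]
    SummarizedExperiment::assay(out, "counts") <-
        rar[keep, , drop = FALSE]
    validObject(out)
    out
}

#' Occupancy (prevalence) filter
#'
#' Keeps OTUs present (count > 0) in at least
#' \code{ceiling(minFraction * n_samples)} samples; the usual reading of
#' "discard OTUs with a frequency below 10 percent" in molecular ecological
#' network pipelines.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param minFraction occupancy threshold in (0, 1]; default 0.10.
#' @return filtered \linkS4class{OtuExperiment}
#' @export
prevalenceFilter <- function(x, minFraction = 0.10) {
    if (minFraction <= 0 || minFraction > 1)
        stop("minFraction must lie in (0, 1]")
    cnt <- otuCounts(x)
    need <- ceiling(minFraction * ncol(cnt))
    keep <- rowSums(cnt > 0) >= need
    if (!any(keep))
        stop("prevalence filter at ", minFraction,
             " removed every OTU; lower the threshold")
    x[keep, ]
}

#' Relative abundance, optionally aggregated to a taxonomic rank
#'
#' Aggregates counts by lineage prefix at the requested rank, then
#' normalizes each sample column to sum to 1. OTUs with an unparseable or
#' missing rank fall into an \code{"unclassified_<parent>"} bucket.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param level \code{"otu"} or one of kingdom, phylum, class, order,
#'   family, genus, species.
#' @return proportion matrix, features x samples, columns summing to 1.
#' @export
relativeAbundance <- function(x, level = "otu") {
    cnt <- otuCounts(x)
    level <- match.arg(tolower(level), c("otu", RANKS))
    if (level != "otu") {
        ranks <- parseLineages(unname(taxonomy(x)))
        grp <- ranks[, level]
        cnt <- rowsum(cnt, grp)
    }
    totals <- colSums(cnt)
    if (any(totals == 0)) stop("sample with zero total count")
    sweep(cnt, 2, totals, "/")
}
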