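## Internal helpers shared across modules.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
           "species")
RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

emptyLineage <- function() paste0(RANK_PREFIXES, collapse = ";")

## Deterministic child seed: one master seed split per named stage so that
## stages draw from independent streams without cross-coupling.
childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

## Parse lineage strings into a 7-column rank matrix. Missing or unparseable
## ranks become "unclassified_<parent>".
parseLineages <- function(lineages) {
    out <- matrix("", length(lineages), length(RANKS),
                  dimnames = list(NULL, RANKS))
    for (i in seq_along(lineages)) {
        parts <- strsplit(lineages[i], ";", fixed = TRUE)[[1]]
        parts <- trimws(parts)
        vals <- character(length(RANKS))
        parent <- "root"
        for (r in seq_along(RANKS)) {
            v <- if (r <= length(parts)) sub(RANK_PREFIXES[r], "",
                                             parts[r], fixed = TRUE) else ""
            if (r <= length(parts) &&
                !startsWith(parts[r], RANK_PREFIXES[r]) &&
                nzchar(parts[r]))
                v <- ""                      # wrong prefix: unparseable
            if (!nzchar(v)) v <- paste0("unclassified_", parent)
            vals[r] <- v
            parent <- v
        }
        out[i, ] <- vals
    }
    out
}

## Upper-triangle index pairs of an n x n matrix as a 2-column matrix.
upperPairs <- function(n) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

## Count, for each x, how many values of sorted vector v are >= x
## (exact on ties).
countGE <- function(x, vSorted) {
    length(vSorted) - findInterval(x, vSorted, left.open = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
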