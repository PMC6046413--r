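#' Read a sample-by-taxon count table
#'
#' Parses a TSV or CSV table with one row per sample: metadata columns first
#' (at least \code{sample_id}, \code{carrier}, \code{biotope}; optionally
#' \code{sex}), then one column per taxon holding read counts. Empty count
#' cells are treated as 0 reads; non-integer counts are a parse error that
#' names the offending row and column.
#'
#' @param path path to a delimited text file; the delimiter is taken from
#'   the extension (".csv" means comma, anything else tab) unless \code{sep}
#'   is given.
#' @param metadataColumns names of the leading metadata columns. The first
#'   must be the sample identifier.
#' @param taxonRank rank of the taxon columns (see \code{\link{ReadMatrix}}).
#' @param sep optional field separator overriding the extension heuristic.
#'
#' @return a \linkS4class{ReadMatrix}.
#' @seealso \code{\link{writeReadMatrix}} for the inverse.
#' @export
readReadMatrix <- function(path,
                           metadataColumns = c("sample_id", "carrier",
                                               "biotope", "sex"),
                           taxonRank = "genus", sep = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "")
    missing_md <- setdiff(intersect(metadataColumns,
                                    c("sample_id", "carrier", "biotope")),
                          colnames(df))
    if (length(missing_md))
        stop("metadata columns missing from ", path, ": ",
             paste(missing_md, collapse = ", "))
    metadataColumns <- intersect(metadataColumns, colnames(df))
    idcol <- metadataColumns[1L]
    ids <- df[[idcol]]
    if (anyDuplicated(ids))
        stop("duplicate sample_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    taxcols <- setdiff(colnames(df), metadataColumns)
    if (anyDuplicated(taxcols))
        stop("duplicate taxon columns: ",
             paste(unique(taxcols[duplicated(taxcols)]), collapse = ", "))
    cts <- matrix(0L, nrow = length(taxcols), ncol = nrow(df),
                  dimnames = list(taxcols, ids))
    for (tc in taxcols) {
        raw <- df[[tc]]
        raw[is.na(raw) | trimws(raw) == ""] <- "0"
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(val) | val != round(val) | val < 0)
        if (length(bad))
            stop(sprintf(
                "non-integer read count '%s' at sample '%s', taxon '%s'",
                raw[bad[1L]], ids[bad[1L]], tc))
        cts[tc, ] <- as.integer(val)
    }
    md <- df[setdiff(metadataColumns, idcol)]
    rownames(md) <- ids
    ReadMatrix(cts, md, taxonRank = taxonRank)
}

#' Write a ReadMatrix as a delimited text table
#'
#' Inverse of \code{\link{readReadMatrix}}: samples in rows, metadata
#' columns first, then taxon counts. Round-tripping preserves the matrix
#' exactly.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @param path output file path (".csv" writes comma-separated, otherwise
#'   tab-separated).
#' @return \code{path}, invisibly.
#' @export
writeReadMatrix <- function(x, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- intersect(c("carrier", "biotope", "sex"), colnames(cd))
    out <- cbind(data.frame(sample_id = colnames(x),
                            stringsAsFactors = FALSE),
                 cd[, keep, drop = FALSE],
                 as.data.frame(t(readCounts(x)), check.names = FALSE))
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Merge paired PCR replicates by the consistency rule
#'
#' A sample is scored positive for a taxon only when both PCR replicates are
#' positive; consistent detections are combined by adding the read numbers
#' of the two replicates, and inconsistent ones are zeroed. Both replicate
#' matrices must cover the same samples and taxa.
#'
#' @param repA,repB \linkS4class{ReadMatrix} objects holding replicate A and
#'   B of the same samples.
#' @return a merged \linkS4class{ReadMatrix} with \code{repA}'s metadata.
#' @examples
#' # a taxon with 5 reads in one replicate and 3 in the other keeps 8;
#' # 5 and 0 is inconsistent and is zeroed.
#' @export
mergeReplicates <- function(repA, repB) {
    if (!setequal(sampleIDs(repA), sampleIDs(repB)))
        stop("replicate matrices do not cover the same samples")
    if (!setequal(taxa(repA), taxa(repB)))
        stop("replicate matrices do not cover the same taxa")
    a <- readCounts(repA)
    b <- readCounts(repB)[taxa(repA), sampleIDs(repA), drop = FALSE]
    merged <- (a + b) * (a > 0 & b > 0)
    storage.mode(merged) <- "integer"
    out <- repA
    SummarizedExperiment::assay(out, "counts") <- merged
    metadata(out)$filterReport <- c(metadata(out)$filterReport, list(list(
        filter = "merge_replicates",
        n_occurrences_zeroed = sum((a > 0) != (b > 0)))))
    out
}

#' Taxon accumulation curve for one sample
#'
#' Expected number of distinct taxa observed when the sample's reads are
#' subsampled without replacement to a grid of depths, used to judge whether
#' sequencing depth saturated the taxon catalogue of a carrier. The default
#' is the exact hypergeometric expectation
#' \deqn{E[S(d)] = \sum_g \left(1 - \binom{N - n_g}{d} / \binom{N}{d}\right)}
#' where \eqn{N} is the sample's total reads and \eqn{n_g} the reads of
#' taxon \eqn{g}; \code{method = "montecarlo"} estimates the same quantity
#' by repeated subsampling.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @param sampleID the sample to rarefy.
#' @param nPoints number of depths on the grid (from 1 to the total reads).
#' @param method \code{"analytic"} (default, deterministic) or
#'   \code{"montecarlo"}.
#' @param nDraws Monte-Carlo subsampling repetitions.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return \code{data.frame} with columns \code{depth} and \code{taxa}
#'   (expected distinct taxa at that depth); nondecreasing in depth.
#' @export
accumulationCurve <- function(x, sampleID, nPoints = 20,
                              method = c("analytic", "montecarlo"),
                              nDraws = 1000, seed = 1) {
    method <- match.arg(method)
    if (!sampleID %in% sampleIDs(x))
        stop("unknown sample: ", sampleID)
    n <- readCounts(x)[, sampleID]
    n <- n[n > 0]
    N <- sum(n)
    if (N == 0)
        stop("sample has no reads: ", sampleID)
    depths <- unique(round(seq(1, N, length.out = min(nPoints, N))))
    if (method == "analytic") {
        taxa_exp <- vapply(depths, function(d)
            sum(1 - exp(lchoose(N - n, d) - lchoose(N, d))), 0)
    } else {
        set.seed(seed)
        pool <- rep.int(seq_along(n), n)
        taxa_exp <- vapply(depths, function(d)
            mean(vapply(seq_len(nDraws), function(i)
                length(unique(sample(pool, d))), 0L)), 0)
    }
    data.frame(depth = depths, taxa = taxa_exp)
}

#' Aggregate an OTU-level matrix to a higher rank
#'
#' Sums read counts of OTUs mapping to the same higher-rank taxon, using a
#' two-column mapping (OTU id, target taxon). OTUs missing from the mapping
#' are dropped with a note in the filter report (they are the "unassigned"
#' OTUs at that rank).
#'
#' @param x a \linkS4class{ReadMatrix} at OTU rank.
#' @param mapping \code{data.frame} whose first column matches \code{taxa(x)}
#'   and whose second column gives the target taxon name.
#' @param taxonRank rank of the aggregated rows.
#' @return an aggregated \linkS4class{ReadMatrix}.
#' @export
aggregateTaxa <- function(x, mapping, taxonRank = "genus") {
    map <- stats::setNames(as.character(mapping[[2L]]),
                           as.character(mapping[[1L]]))
    known <- intersect(taxa(x), names(map))
    cts <- readCounts(x)[known, , drop = FALSE]
    agg <- rowsum(cts, group = map[known])
    storage.mode(agg) <- "integer"
    out <- ReadMatrix(agg, SummarizedExperiment::colData(x),
                      taxonRank = taxonRank)
    metadata(out)$filterReport <- c(metadata(x)$filterReport, list(list(
        filter = "aggregate_taxa", rank = taxonRank,
        n_unmapped_dropped = length(taxa(x)) - length(known))))
    out
}
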