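#' Filtering rules for read matrices
#'
#' Three successive rules clean a read matrix before network construction:
#' (i) \code{dropUnassigned} discards taxa that could not be assigned at the
#' working rank; (ii) \code{dropSingletons} removes taxa detected in exactly
#' one sample of the whole set; (iii) \code{lowReadCutoff} zeroes, per
#' taxon, the occurrences whose read count falls strictly below a low
#' percentile of that taxon's nonzero read counts, so each taxon gets its
#' own cut-off level. Every rule appends an entry to
#' \code{\link{filterReport}}.
#'
#' All three are idempotent, never increase a count and never add taxa.
#' \code{applyFilters} chains them in the fixed order (i) -> (ii) -> (iii);
#' singleton status is not re-evaluated after the cutoff step unless
#' \code{iterate = TRUE}, which repeats the singleton + cutoff pair until a
#' fixed point.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @param assigned character vector of taxon names with a valid assignment
#'   at the working rank; taxa outside it are removed. \code{NULL} keeps
#'   everything (useful when the input table is already genus-level).
#' @param percentile percentile (0-100) of each taxon's \emph{nonzero} read
#'   counts used as its cutoff; occurrences strictly below are zeroed.
#'   The percentile uses linear interpolation between order statistics
#'   (\code{stats::quantile} type 7). Default 10. Zeros are excluded from
#'   the distribution: they are non-detections, not low reads.
#' @param iterate repeat singleton removal and cutoff until stable.
#' @return the filtered \linkS4class{ReadMatrix}.
#' @name filtering
NULL

.append_report <- function(x, entry) {
    metadata(x)$filterReport <- c(metadata(x)$filterReport, list(entry))
    x
}

#' @rdname filtering
#' @export
dropUnassigned <- function(x, assigned = NULL) {
    if (is.null(assigned))
        return(.append_report(x, list(filter = "drop_unassigned",
                                      n_unassigned_removed = 0L)))
    keep <- taxa(x) %in% assigned
    out <- x[keep, ]
    .append_report(out, list(filter = "drop_unassigned",
                             n_unassigned_removed = sum(!keep),
                             removed = taxa(x)[!keep]))
}

#' @rdname filtering
#' @export
dropSingletons <- function(x) {
    occ <- rowSums(readCounts(x) > 0)
    keep <- occ != 1L
    out <- x[keep, ]
    .append_report(out, list(filter = "drop_singletons",
                             n_singletons_removed = sum(!keep),
                             removed = taxa(x)[!keep]))
}

#' @details A taxon's cutoff is \emph{established once}, from the read
#' distribution seen when the filter first runs, and recorded in the filter
#' report. Re-applying the filter at the same percentile reuses the
#' established cutoffs rather than re-deriving them from the already
#' censored distribution (which would keep eroding its lower tail), so the
#' operation is idempotent.
#'
#' @rdname filtering
#' @export
lowReadCutoff <- function(x, percentile = 10) {
    stopifnot(percentile >= 0, percentile < 100)
    cts <- readCounts(x)
    prior <- NULL
    for (entry in rev(filterReport(x)))
        if (identical(entry$filter, "low_read_cutoff") &&
            identical(entry$percentile, percentile)) {
            prior <- entry$per_taxon_cutoff
            break
        }
    cutoffs <- apply(cts, 1L, function(v) {
        nz <- v[v > 0]
        if (length(nz) == 0) 0 else
            unname(stats::quantile(nz, percentile / 100, type = 7))
    })
    if (!is.null(prior)) {
        keep <- intersect(names(cutoffs), names(prior))
        cutoffs[keep] <- prior[keep]
    }
    zeroed <- 0L
    for (i in seq_len(nrow(cts))) {
        below <- cts[i, ] > 0 & cts[i, ] < cutoffs[i]
        zeroed <- zeroed + sum(below)
        cts[i, below] <- 0L
    }
    out <- x
    SummarizedExperiment::assay(out, "counts") <- cts
    .append_report(out, list(filter = "low_read_cutoff",
                             percentile = percentile,
                             per_taxon_cutoff = cutoffs,
                             n_occurrences_zeroed = zeroed))
}

#' @rdname filtering
#' @export
applyFilters <- function(x, assigned = NULL, percentile = 10,
                         iterate = FALSE) {
    out <- dropUnassigned(x, assigned)
    out <- dropSingletons(out)
    out <- lowReadCutoff(out, percentile)
    if (iterate) {
        repeat {
            before <- readCounts(out)
            out <- dropSingletons(out)
            out <- lowReadCutoff(out, percentile)
            after <- readCounts(out)
            if (nrow(before) == nrow(after) && all(before == after))
                break
        }
    }
    out
}

#' Presence/absence matrix
#'
#' Logical taxa x samples matrix: a cell is \code{TRUE} when the (filtered)
#' read count is nonzero. This is the basis of all network construction:
#' two taxa are linked when simultaneously detected in a single carrier.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @return logical matrix with the same dimnames as the counts.
#' @export
presenceMatrix <- function(x) {
    readCounts(x) > 0
}
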