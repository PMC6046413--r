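#' @importFrom methods setGeneric setMethod show
NULL

#' Accessors for ReadMatrix
#'
#' \code{taxa} returns the taxon (row) names; \code{sampleIDs} the sample
#' (column) ids; \code{carriers} and \code{biotopes} the per-sample
#' covariates; \code{taxonRank} the rank of the rows; \code{readCounts} the
#' counts matrix (taxa x samples); \code{filterReport} the accumulated
#' filtering audit trail (a list, one entry per filter applied).
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @return character vectors, an integer matrix, or a list, respectively.
#' @name ReadMatrix-accessors
#' @aliases taxa sampleIDs carriers biotopes taxonRank readCounts
#'   filterReport
NULL

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("carriers", function(x) standardGeneric("carriers"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("biotopes", function(x) standardGeneric("biotopes"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("taxonRank", function(x) standardGeneric("taxonRank"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname ReadMatrix-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' Network accessors
#'
#' \code{asGraph} extracts the underlying \pkg{igraph} object of a network;
#' \code{stratum} the (carrier, biotope) pair of a
#' \linkS4class{CooccurrenceNetwork}; \code{nodeMetrics} the per-node metric
#' table (after \code{\link{computeNodeMetrics}}).
#'
#' @param x a \linkS4class{CooccurrenceNetwork} or
#'   \linkS4class{CarrierNetwork}.
#' @return an \code{igraph}, a named character vector, or a
#'   \code{DataFrame}.
#' @name network-accessors
#' @aliases asGraph stratum nodeMetrics
NULL

#' @rdname network-accessors
#' @export
setGeneric("asGraph", function(x) standardGeneric("asGraph"))

#' @rdname network-accessors
#' @export
setGeneric("stratum", function(x) standardGeneric("stratum"))

#' @rdname network-accessors
#' @export
setGeneric("nodeMetrics", function(x) standardGeneric("nodeMetrics"))

setMethod("taxa", "ReadMatrix", function(x) rownames(x))
setMethod("sampleIDs", "ReadMatrix", function(x) colnames(x))
setMethod("carriers", "ReadMatrix", function(x) {
    v <- as.character(SummarizedExperiment::colData(x)$carrier)
    names(v) <- colnames(x)
    v
})
setMethod("biotopes", "ReadMatrix", function(x) {
    v <- as.character(SummarizedExperiment::colData(x)$biotope)
    names(v) <- colnames(x)
    v
})
setMethod("taxonRank", "ReadMatrix", function(x) metadata(x)$taxonRank)
setMethod("readCounts", "ReadMatrix",
    function(x) SummarizedExperiment::assay(x, "counts"))
setMethod("filterReport", "ReadMatrix",
    function(x) metadata(x)$filterReport)

setMethod("asGraph", "CooccurrenceNetwork", function(x) x@graph)
setMethod("asGraph", "CarrierNetwork", function(x) x@graph)
setMethod("stratum", "CooccurrenceNetwork", function(x) x@stratum)
setMethod("nodeMetrics", "CooccurrenceNetwork", function(x) x@nodeMetrics)

setMethod("show", "ReadMatrix", function(object) {
    cts <- readCounts(object)
    cat(sprintf("ReadMatrix: %d %s taxa x %d samples, %s total reads\n",
                nrow(object), taxonRank(object), ncol(object),
                format(sum(as.numeric(cts)), big.mark = ",")))
    tab <- table(carriers(object), biotopes(object))
    cat("samples per stratum:\n")
    print(tab)
    nf <- length(filterReport(object))
    if (nf > 0)
        cat(sprintf("filters applied: %s\n",
                    paste(vapply(filterReport(object), `[[`, "", "filter"),
                          collapse = " -> ")))
    invisible(object)
})

setMethod("show", "CooccurrenceNetwork", function(object) {
    g <- object@graph
    cat(sprintf("CooccurrenceNetwork [%s, %s]: %d nodes, %d links\n",
                object@stratum[["carrier"]], object@stratum[["biotope"]],
                igraph::vcount(g), igraph::ecount(g)))
    if (nrow(object@nodeMetrics) > 0) {
        k <- length(unique(object@nodeMetrics$community))
        cat(sprintf("node metrics computed; %d communities\n", k))
    }
    invisible(object)
})

setMethod("show", "CarrierNetwork", function(object) {
    g <- object@graph
    tab <- table(igraph::V(g)$carrier)
    cat(sprintf("CarrierNetwork [%s]: %d individuals (%s), %d links\n",
                object@biotope, igraph::vcount(g),
                paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
                igraph::ecount(g)))
    if (length(object@communities) > 0)
        cat(sprintf("%d communities detected\n",
                    length(unique(object@communities))))
    invisible(object)
})
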