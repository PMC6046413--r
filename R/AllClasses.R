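#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom methods setClass setValidity new validObject is slot
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setOldClass("igraph")
setOldClass("phylo")

#' ReadMatrix: samples-by-taxa read counts with carrier metadata
#'
#' A \code{ReadMatrix} holds the central exchange object of the framework: a
#' taxa x samples matrix of sequencing read counts (assay \code{"counts"})
#' together with per-sample metadata. It extends
#' \linkS4class{SummarizedExperiment}, so all the usual subsetting,
#' \code{assay()}, \code{colData()} and \code{metadata()} machinery applies.
#' Rows are taxa (usually bacterial genera), columns are individual carriers
#' (e.g. ticks or voles).
#'
#' Required sample covariates in \code{colData}: \code{carrier} (which host
#' species the sample comes from) and \code{biotope} (habitat stratum);
#' \code{sex} is optional. The taxonomic rank of the rows is stored in
#' \code{metadata(x)$taxonRank}. Filtering functions append an audit trail
#' to \code{metadata(x)$filterReport} (see \code{\link{filterReport}}).
#'
#' @seealso \code{\link{ReadMatrix}} (constructor),
#'   \code{\link{readReadMatrix}}, \code{\link{simulateReadMatrix}}
#' @name ReadMatrix-class
#' @aliases ReadMatrix-class
#' @exportClass ReadMatrix
setClass("ReadMatrix", contains = "SummarizedExperiment")

setValidity("ReadMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(cts))
            msg <- c(msg, "'counts' must be numeric")
        else {
            if (any(cts < 0, na.rm = TRUE))
                msg <- c(msg, "'counts' must be non-negative")
            if (any(cts != round(cts), na.rm = TRUE))
                msg <- c(msg, "'counts' must be whole numbers of reads")
            if (anyNA(cts))
                msg <- c(msg, "'counts' must not contain NA")
        }
    }
    cd <- SummarizedExperiment::colData(object)
    for (f in c("carrier", "biotope"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", f))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "taxa (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a ReadMatrix
#'
#' @param counts integer matrix of read counts, taxa in rows, samples in
#'   columns. Dimnames are mandatory (taxa and sample ids).
#' @param sampleData a \code{data.frame} or \code{DataFrame} with one row per
#'   sample, containing at least \code{carrier} and \code{biotope} columns.
#'   A \code{sex} column is carried along if present.
#' @param taxonRank rank of the row taxa; one of \code{"genus"},
#'   \code{"OTU"}, \code{"family"}, \code{"order"}.
#'
#' @return a validated \linkS4class{ReadMatrix}.
#' @examples
#' cts <- matrix(c(5L, 0L, 2L, 7L, 1L, 0L), nrow = 3,
#'               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' md <- data.frame(carrier = c("tick", "vole"),
#'                  biotope = c("forest", "forest"),
#'                  row.names = c("s1", "s2"))
#' rm <- ReadMatrix(cts, md)
#' taxa(rm)
#' @export
ReadMatrix <- function(counts, sampleData,
                       taxonRank = c("genus", "OTU", "family", "order")) {
    taxonRank <- match.arg(taxonRank)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    sampleData <- as(sampleData, "DataFrame")
    if (!is.null(rownames(sampleData)) && !is.null(colnames(counts))) {
        if (!setequal(rownames(sampleData), colnames(counts)))
            stop("sample ids of 'counts' and 'sampleData' disagree")
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
    if ("sex" %in% colnames(sampleData)) {
        sx <- as.character(sampleData$sex)
        sx[is.na(sx)] <- "unknown"
        sampleData$sex <- sx
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = sampleData)
    out <- new("ReadMatrix", se)
    metadata(out)$taxonRank <- taxonRank
    metadata(out)$filterReport <- list()
    validObject(out)
    out
}

#' CooccurrenceNetwork: weighted genus co-occurrence graph for one stratum
#'
#' Undirected weighted graph over taxa observed in one carrier-by-biotope
#' stratum. An edge joins two taxa detected together in at least one sample;
#' its weight is the number of samples in which the pair co-occurs. Node
#' metrics (weighted degree WD, betweenness centrality BNC, local clustering
#' coefficient CC, PageRank PR, community label) are filled in by
#' \code{\link{computeNodeMetrics}} and retrieved with
#' \code{\link{nodeMetrics}}.
#'
#' @name CooccurrenceNetwork-class
#' @aliases CooccurrenceNetwork-class
#' @exportClass CooccurrenceNetwork
setClass("CooccurrenceNetwork",
    slots = c(graph = "igraph", stratum = "character",
              nodeMetrics = "DataFrame"))

setValidity("CooccurrenceNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g))
        msg <- c(msg, "graph must have no self-edges")
    if (igraph::ecount(g) > 0) {
        w <- igraph::E(g)$weight
        if (is.null(w) || any(w < 1))
            msg <- c(msg, "edge weights must be co-occurrence counts >= 1")
    }
    nm <- object@nodeMetrics
    if (nrow(nm) > 0 &&
        !identical(sort(rownames(nm)), sort(igraph::V(g)$name)))
        msg <- c(msg, "nodeMetrics must be keyed exactly by the node names")
    if (length(msg)) msg else TRUE
})

#' CarrierNetwork: individuals linked by shared bacterial genera
#'
#' Undirected weighted graph whose nodes are individual samples (ticks and
#' voles of one biotope) and whose edge weights count the bacterial genera
#' shared by the two individuals. Carrier labels are stored as the vertex
#' attribute \code{carrier}; community labels are added by
#' \code{\link{detectCarrierCommunities}}.
#'
#' @name CarrierNetwork-class
#' @aliases CarrierNetwork-class
#' @exportClass CarrierNetwork
setClass("CarrierNetwork",
    slots = c(graph = "igraph", biotope = "character",
              communities = "integer"))

setValidity("CarrierNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g))
        msg <- c(msg, "graph must have no self-edges")
    if (igraph::ecount(g) > 0 && any(igraph::E(g)$weight < 1))
        msg <- c(msg, "edge weights must be shared-genus counts >= 1")
    if (length(object@communities) > 0 &&
        !identical(sort(names(object@communities)),
                   sort(igraph::V(g)$name)))
        msg <- c(msg, "communities must be keyed by the node names")
    if (length(msg)) msg else TRUE
})
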