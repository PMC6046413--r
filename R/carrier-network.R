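#' Build the individual-carrier similarity network of a biotope
#'
#' Nodes are the individual samples (ticks and voles together) of one
#' biotope; each pair sharing at least one bacterial genus is linked, with
#' the edge weight equal to the number of shared genera. Pairs sharing
#' nothing get no edge. An optional minimum-sharing threshold prunes weak
#' links.
#'
#' @param x a filtered \linkS4class{ReadMatrix}.
#' @param biotope the biotope to analyse (\code{NULL} uses all samples).
#' @param minShared drop edges with fewer shared genera than this
#'   (default 1, i.e. no pruning).
#' @return a \linkS4class{CarrierNetwork} whose graph carries a
#'   \code{carrier} vertex attribute.
#' @export
buildCarrierNetwork <- function(x, biotope = NULL, minShared = 1) {
    sel <- if (is.null(biotope)) rep(TRUE, ncol(x))
           else biotopes(x) == biotope
    if (sum(sel) < 2)
        stop("need at least 2 samples in the biotope")
    P <- presenceMatrix(x)[, sel, drop = FALSE]
    S <- crossprod(P * 1L)          # samples x samples shared-genus counts
    diag(S) <- 0
    S[S < minShared] <- 0
    g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                             weighted = TRUE)
    g <- igraph::set_vertex_attr(g, "carrier",
                                 value = unname(carriers(x)[sel]))
    new("CarrierNetwork", graph = g,
        biotope = biotope %||% "all", communities = integer())
}

#' Communities of individual carriers
#'
#' Applies the same modularity-maximization contract as
#' \code{\link{detectCommunities}} to the mixed tick+vole similarity graph
#' of a biotope, so that a separation of the two carrier species into
#' different communities is an outcome, not an assumption. The labels are
#' stored in the returned network and as a \code{community} vertex
#' attribute.
#'
#' @param net a \linkS4class{CarrierNetwork}.
#' @param resolution,seed,method see \code{\link{detectCommunities}}.
#' @return the network with its \code{communities} slot filled.
#' @export
detectCarrierCommunities <- function(net, resolution = 1, seed = 1,
                                     method = "louvain") {
    labels <- detectCommunities(net, resolution = resolution, seed = seed,
                                method = method)
    net@communities <- labels
    net@graph <- igraph::set_vertex_attr(
        net@graph, "community",
        value = unname(labels[igraph::V(net@graph)$name]))
    validObject(net)
    net
}

#' Carrier community membership
#'
#' @param net a \linkS4class{CarrierNetwork} after
#'   \code{\link{detectCarrierCommunities}}.
#' @return named integer vector of community labels per sample.
#' @export
carrierCommunities <- function(net) {
    if (length(net@communities) == 0)
        stop("run detectCarrierCommunities() first")
    net@communities
}
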