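#' Build the genus co-occurrence network of one stratum
#'
#' Restricts the read matrix to the samples of one carrier-by-biotope
#' stratum and links every pair of taxa detected together in at least one
#' sample; the edge weight is the number of samples in which the pair
#' co-occurs. Taxa present in the stratum but never co-occurring with
#' another taxon are kept as isolated (degree-0) nodes; taxa absent from
#' the stratum are excluded.
#'
#' @param x a \linkS4class{ReadMatrix} (normally after
#'   \code{\link{applyFilters}}).
#' @param carrier,biotope stratum selectors; \code{NULL} keeps all samples
#'   for that factor (a pooled network).
#' @return a \linkS4class{CooccurrenceNetwork}.
#' @examples
#' cts <- matrix(c(1L,1L,0L, 1L,1L,0L, 1L,0L,1L), nrow = 3,
#'               dimnames = list(c("a","b","c"), c("S1","S2","S3")))
#' md <- data.frame(carrier = "tick", biotope = "forest",
#'                  row.names = colnames(cts))
#' net <- buildCooccurrenceNetwork(ReadMatrix(cts, md))
#' weightedDegree(net)   # a: 3, b: 2, c: 1
#' @export
buildCooccurrenceNetwork <- function(x, carrier = NULL, biotope = NULL) {
    sel <- rep(TRUE, ncol(x))
    if (!is.null(carrier)) sel <- sel & carriers(x) == carrier
    if (!is.null(biotope)) sel <- sel & biotopes(x) == biotope
    if (!any(sel))
        stop(sprintf("empty stratum: carrier=%s, biotope=%s",
                     carrier %||% "*", biotope %||% "*"))
    P <- presenceMatrix(x)[, sel, drop = FALSE]
    P <- P[rowSums(P) > 0, , drop = FALSE]
    if (nrow(P) == 0)
        stop("no taxa detected in the stratum")
    # pairwise co-detection counts; diagonal (occurrence counts) discarded
    M <- tcrossprod(P * 1L)
    diag(M) <- 0
    g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                             weighted = TRUE)
    new("CooccurrenceNetwork", graph = g,
        stratum = c(carrier = carrier %||% "all",
                    biotope = biotope %||% "all"),
        nodeMetrics = S4Vectors::DataFrame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node-level network indexes
#'
#' \code{weightedDegree} (WD) is the sum of a node's incident edge weights
#' and measures how often a taxon is co-detected with others.
#' \code{betweennessCentrality} (BNC) counts, for each node, the shortest
#' paths between other node pairs passing through it (Brandes' exact
#' algorithm; by default on unweighted shortest paths and unnormalized).
#' \code{clusteringCoefficient} (CC) is the local transitivity
#' \eqn{2 e_N / (k (k-1))} on the binarized graph, 0 for nodes of degree
#' below 2. \code{pageRank} (PR) is the stationary probability of a damped
#' random walk whose transition probabilities are proportional to edge
#' weights; isolated nodes receive teleport-only mass and the values sum
#' to 1.
#'
#' @param net a \linkS4class{CooccurrenceNetwork} or
#'   \linkS4class{CarrierNetwork}.
#' @param weighted use edge weights (as affinities; shortest-path distance
#'   is 1/weight) for betweenness. Default \code{FALSE}: topological
#'   variant.
#' @param normalized divide betweenness by the number of ordered node pairs.
#' @param damping PageRank damping factor.
#' @return named numeric vector over the network's nodes.
#' @name node-metrics
NULL

#' @rdname node-metrics
#' @export
weightedDegree <- function(net) {
    g <- asGraph(net)
    igraph::strength(g, weights = igraph::E(g)$weight)
}

#' @rdname node-metrics
#' @export
betweennessCentrality <- function(net, weighted = FALSE,
                                  normalized = FALSE) {
    g <- asGraph(net)
    w <- if (weighted) 1 / igraph::E(g)$weight else NA
    igraph::betweenness(g, directed = FALSE, weights = w,
                        normalized = normalized)
}

#' @rdname node-metrics
#' @export
clusteringCoefficient <- function(net) {
    g <- asGraph(net)
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    stats::setNames(cc, igraph::V(g)$name)
}

#' @rdname node-metrics
#' @export
pageRank <- function(net, damping = 0.85) {
    g <- asGraph(net)
    pr <- igraph::page_rank(g, damping = damping,
                            weights = igraph::E(g)$weight)$vector
    pr / sum(pr)
}

#' Modularity communities of co-occurring taxa
#'
#' Partitions the nodes into communities maximizing Newman's modularity on
#' the edge weights, via the Louvain multi-level heuristic with a fixed RNG
#' seed. Labels are integers \code{0..k-1} ordered by decreasing community
#' size; ties broken by the smallest member name.
#'
#' @param net a \linkS4class{CooccurrenceNetwork} or
#'   \linkS4class{CarrierNetwork}.
#' @param resolution Louvain resolution parameter (1 recovers plain
#'   modularity).
#' @param seed integer RNG seed making the heuristic deterministic.
#' @param method \code{"louvain"} (default) or \code{"greedy"}
#'   (Clauset-Newman-Moore agglomeration).
#' @return named integer vector of community labels.
#' @export
detectCommunities <- function(net, resolution = 1, seed = 1,
                              method = c("louvain", "greedy")) {
    method <- match.arg(method)
    g <- asGraph(net)
    w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
    set.seed(seed)
    cm <- if (method == "louvain")
        igraph::cluster_louvain(g, weights = w, resolution = resolution)
    else
        igraph::cluster_fast_greedy(g, weights = w)
    .relabel_communities(igraph::membership(cm))
}

# relabel raw memberships 0..k-1 by decreasing size, ties by smallest name
.relabel_communities <- function(memb) {
    nm <- names(memb)
    groups <- split(nm, memb)
    ord <- order(-lengths(groups),
                 vapply(groups, function(g) sort(g)[1L], ""))
    newlab <- integer(length(memb))
    names(newlab) <- nm
    for (i in seq_along(ord))
        newlab[groups[[ord[i]]]] <- i - 1L
    newlab
}

#' Compute and attach all node metrics
#'
#' Convenience wrapper filling the \code{\link{nodeMetrics}} table of a
#' co-occurrence network with WD, BNC, CC, PR and the community label, the
#' per-genus indexes used throughout the downstream analyses.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param damping PageRank damping factor.
#' @param resolution,seed passed to \code{\link{detectCommunities}}.
#' @param weightedBetweenness use weighted shortest paths for BNC.
#' @return the network with its \code{nodeMetrics} slot filled.
#' @export
computeNodeMetrics <- function(net, damping = 0.85, resolution = 1,
                               seed = 1, weightedBetweenness = FALSE) {
    wd <- weightedDegree(net)
    nm <- S4Vectors::DataFrame(
        WD = wd,
        BNC = betweennessCentrality(net, weighted = weightedBetweenness),
        CC = clusteringCoefficient(net),
        PR = pageRank(net, damping = damping),
        community = detectCommunities(net, resolution = resolution,
                                      seed = seed),
        row.names = names(wd))
    net@nodeMetrics <- nm
    validObject(net)
    net
}

#' Fit a power law to weighted-degree values
#'
#' Tests the scale-free character of a network by fitting a continuous
#' power law to its weighted degrees with the Clauset-Shalizi-Newman
#' procedure: the exponent is the maximum-likelihood estimate
#' \eqn{\hat\gamma = 1 + n / \sum \ln(x_i/x_{min})} and \eqn{x_{min}} is
#' chosen by minimizing the Kolmogorov-Smirnov distance between the data
#' tail and the fitted law. A log-log regression slope on the empirical
#' survival function is reported alongside for comparability with older
#' practice.
#'
#' @param wd positive numeric vector (at least 10 values).
#' @param xmin optional fixed lower bound, skipping the KS scan.
#' @return list with \code{gamma}, \code{xmin}, \code{ks_distance},
#'   \code{n_tail}, \code{loglik} and \code{gamma_regression}.
#' @export
fitPowerLaw <- function(wd, xmin = NULL) {
    wd <- wd[wd > 0]
    if (length(wd) < 10)
        stop("need at least 10 positive values to fit a power law")
    if (max(wd) == min(wd))
        stop("degenerate input: all values equal, zero log-spread")
    fit <- igraph::fit_power_law(wd, xmin = xmin,
                                 implementation = "plfit")
    n_tail <- sum(wd >= fit$xmin)
    if (n_tail < 10) {
        warning("fewer than 10 tail points at selected xmin; ",
                "refitting on the full data with xmin = min")
        fit <- igraph::fit_power_law(wd, xmin = min(wd),
                                     implementation = "plfit")
        n_tail <- length(wd)
    }
    # survival-function regression: log S(x) ~ log x has slope 1 - gamma
    xs <- sort(unique(wd))
    surv <- vapply(xs, function(v) mean(wd >= v), 0)
    sl <- stats::coef(stats::lm(log(surv) ~ log(xs)))[2L]
    list(gamma = fit$alpha, xmin = fit$xmin,
         ks_distance = fit$KS.stat, n_tail = n_tail,
         loglik = fit$logLik, gamma_regression = unname(1 - sl))
}

#' Export a network
#'
#' Writes the graph as GraphML with WD/BNC/CC/PR/community node attributes
#' (when computed) and, optionally, the node-metric table as TSV.
#'
#' @param net a \linkS4class{CooccurrenceNetwork}.
#' @param graphml,tsv output paths (either may be \code{NULL}).
#' @return invisible \code{NULL}.
#' @export
exportNetwork <- function(net, graphml = NULL, tsv = NULL) {
    g <- asGraph(net)
    nm <- nodeMetrics(net)
    if (nrow(nm) > 0) {
        nm <- nm[igraph::V(g)$name, ]
        for (col in colnames(nm))
            g <- igraph::set_vertex_attr(g, col, value = nm[[col]])
    }
    if (!is.null(graphml))
        igraph::write_graph(g, graphml, format = "graphml")
    if (!is.null(tsv) && nrow(nm) > 0) {
        df <- cbind(data.frame(taxon = rownames(nm)), as.data.frame(nm))
        utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(NULL)
}
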