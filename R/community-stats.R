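#' Sorensen similarity of two presence sets
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)} on presence/absence data: 0 for totally
#' dissimilar assemblages, 1 for identical ones.
#'
#' @param setA,setB character vectors (taxon sets); not both empty.
#' @return similarity in [0, 1].
#' @export
sorensen <- function(setA, setB) {
    setA <- unique(setA)
    setB <- unique(setB)
    if (length(setA) + length(setB) == 0)
        stop("both sets are empty")
    2 * length(intersect(setA, setB)) / (length(setA) + length(setB))
}

#' Genus set of a stratum
#'
#' Taxa detected in at least one sample of the selected stratum, the
#' presence pool behind all Sorensen comparisons.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @param carrier,biotope stratum selectors (NULL pools).
#' @return character vector of taxon names.
#' @export
stratumGenusSet <- function(x, carrier = NULL, biotope = NULL) {
    sel <- rep(TRUE, ncol(x))
    if (!is.null(carrier)) sel <- sel & carriers(x) == carrier
    if (!is.null(biotope)) sel <- sel & biotopes(x) == biotope
    P <- presenceMatrix(x)[, sel, drop = FALSE]
    rownames(P)[rowSums(P) > 0]
}

#' Pairwise Sorensen matrix over the carrier-by-biotope groups
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @return symmetric matrix of Sorensen similarities between the genus
#'   pools of every carrier-by-biotope group.
#' @export
sorensenMatrix <- function(x) {
    groups <- unique(paste(carriers(x), biotopes(x), sep = "."))
    pools <- lapply(groups, function(g) {
        p <- strsplit(g, ".", fixed = TRUE)[[1L]]
        stratumGenusSet(x, carrier = p[1L], biotope = p[2L])
    })
    names(pools) <- groups
    m <- diag(1, length(groups))
    dimnames(m) <- list(groups, groups)
    for (i in seq_along(groups))
        for (j in seq_along(groups))
            if (i < j)
                m[i, j] <- m[j, i] <- sorensen(pools[[i]], pools[[j]])
    m
}

#' Shared and exclusive genera between the two carriers
#'
#' Pools genus presence per carrier over all samples and counts the genera
#' found in both, in only one, and the percent shared of the total genus
#' list.
#'
#' @param x a \linkS4class{ReadMatrix} with exactly two carriers.
#' @return list: \code{n_shared}, \code{n_only_<carrier1>},
#'   \code{n_only_<carrier2>}, \code{pct_shared}, plus the genus vectors
#'   \code{shared}, \code{only_<carrier1>}, \code{only_<carrier2>}.
#' @export
sharedExclusive <- function(x) {
    carr <- sort(unique(carriers(x)))
    if (length(carr) != 2)
        stop("need exactly two carriers (found: ",
             paste(carr, collapse = ", "), ")")
    s1 <- stratumGenusSet(x, carrier = carr[1L])
    s2 <- stratumGenusSet(x, carrier = carr[2L])
    shared <- intersect(s1, s2)
    total <- union(s1, s2)
    out <- list(length(shared), length(setdiff(s1, s2)),
                length(setdiff(s2, s1)),
                100 * length(shared) / length(total),
                shared, setdiff(s1, s2), setdiff(s2, s1))
    names(out) <- c("n_shared", paste0("n_only_", carr[1L]),
                    paste0("n_only_", carr[2L]), "pct_shared",
                    "shared", paste0("only_", carr[1L]),
                    paste0("only_", carr[2L]))
    out
}

#' Summaries of carrier communities
#'
#' For each community of the individual-carrier network: its carrier
#' composition, the percent of each carrier's individuals it holds, the
#' number of distinct bacterial genera circulated by its members, Faith's
#' PD of that genus union, and (since "diversity of a community" can also
#' be read as an average) the mean pairwise phylogenetic distance among
#' the union's genera. Communities are sorted by decreasing share of
#' individuals.
#'
#' @param net a \linkS4class{CarrierNetwork} with communities detected.
#' @param x the \linkS4class{ReadMatrix} the network was built from.
#' @param tree genus tree covering every genus detected in the network's
#'   samples.
#' @return \code{data.frame} with one row per community: \code{community},
#'   \code{n_members}, per-carrier member counts and percentages,
#'   \code{pct_individuals}, \code{n_genera}, \code{pd},
#'   \code{mean_pairwise_dist}.
#' @export
summarizeCommunities <- function(net, x, tree) {
    memb <- carrierCommunities(net)
    ids <- names(memb)
    carr <- carriers(x)[ids]
    P <- presenceMatrix(x)[, ids, drop = FALSE]
    miss <- setdiff(rownames(P)[rowSums(P) > 0], tree$tip.label)
    if (length(miss))
        stop("genera missing from tree: ", paste(miss, collapse = ", "))
    carr_levels <- sort(unique(carr))
    carr_totals <- table(factor(carr, levels = carr_levels))
    dmat <- NULL
    rows <- lapply(sort(unique(memb)), function(cm) {
        members <- ids[memb == cm]
        genera <- rownames(P)[rowSums(P[, members, drop = FALSE]) > 0]
        cc <- table(factor(carr[members], levels = carr_levels))
        pd <- if (length(genera)) faithPD(tree, genera) else 0
        mpd <- NA_real_
        if (length(genera) >= 2) {
            if (is.null(dmat))
                dmat <<- ape::cophenetic.phylo(tree)
            sub <- dmat[genera, genera]
            mpd <- mean(sub[upper.tri(sub)])
        }
        row <- data.frame(community = cm,
                          n_members = length(members),
                          pct_individuals = 100 * length(members) /
                              length(ids),
                          n_genera = length(genera), pd = pd,
                          mean_pairwise_dist = mpd)
        for (cl in carr_levels) {
            row[[paste0("n_", cl)]] <- as.integer(cc[[cl]])
            row[[paste0("pct_", cl)]] <-
                100 * cc[[cl]] / max(1L, carr_totals[[cl]])
        }
        row
    })
    out <- do.call(rbind, rows)
    out[order(-out$pct_individuals, out$community), , drop = FALSE]
}

#' Concentration of phylogenetic diversity across communities
#'
#' Quantifies the Pareto-style pattern in which a small fraction of
#' carriers circulates most of the phylogenetic diversity: the largest
#' community (by percent of individuals) is contrasted with all the
#' others, whose PDs are accumulated by summation. A ratio well above 1
#' means the minority of individuals outside the main community carries
#' several times the PD of the majority. The PD of the pooled genus union
#' of the minor communities is reported alongside the summed version.
#'
#' @param summaries output of \code{\link{summarizeCommunities}}.
#' @param tree,x optional; when both are given the pooled-union PD of the
#'   minor communities is computed too.
#' @param net optional \linkS4class{CarrierNetwork} (needed with
#'   \code{tree}/\code{x} for the pooled variant).
#' @return list: \code{major_pct}, \code{major_pd}, \code{minor_pct},
#'   \code{minor_accumulated_pd}, \code{ratio}
#'   (= minor accumulated / major), and \code{minor_pooled_pd} when
#'   computable.
#' @examples
#' # with a major-community PD of 1.25 and minor PDs summing to 6.78 the
#' # ratio is 6.78 / 1.25 = 5.424
#' @export
pdConcentration <- function(summaries, tree = NULL, x = NULL, net = NULL) {
    if (nrow(summaries) < 2)
        stop("need at least 2 communities")
    ord <- order(-summaries$pct_individuals, summaries$community)
    summaries <- summaries[ord, , drop = FALSE]
    major <- summaries[1L, ]
    minor <- summaries[-1L, ]
    out <- list(major_pct = major$pct_individuals,
                major_pd = major$pd,
                minor_pct = sum(minor$pct_individuals),
                minor_accumulated_pd = sum(minor$pd),
                ratio = sum(minor$pd) / major$pd)
    if (!is.null(tree) && !is.null(x) && !is.null(net)) {
        memb <- carrierCommunities(net)
        minor_ids <- names(memb)[memb != major$community]
        P <- presenceMatrix(x)[, minor_ids, drop = FALSE]
        genera <- rownames(P)[rowSums(P) > 0]
        out$minor_pooled_pd <- if (length(genera))
            faithPD(tree, genera) else 0
    }
    out
}
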