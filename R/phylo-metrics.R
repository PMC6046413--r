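#' Newick import/export
#'
#' Thin wrappers around \pkg{ape}'s Newick reader/writer so trees enter and
#' leave the pipeline as plain text. Round-tripping preserves topology and
#' branch lengths to printed precision.
#'
#' @param text a Newick string (or a file path for \code{file}).
#' @param file optional path to read from / write to.
#' @param tree a \code{phylo} object.
#' @return \code{readNewick}: a \code{phylo}; \code{writeNewick}: the Newick
#'   string, invisibly if written to a file.
#' @name newick-io
NULL

#' @rdname newick-io
#' @export
readNewick <- function(text = NULL, file = NULL) {
    tr <- if (!is.null(file)) ape::read.tree(file)
          else ape::read.tree(text = text)
    if (is.null(tr))
        stop("malformed Newick input")
    tr
}

#' @rdname newick-io
#' @export
writeNewick <- function(tree, file = NULL) {
    if (is.null(file))
        return(ape::write.tree(tree))
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration over a symmetric distance matrix (as
#' used to summarize 16S rRNA distances between bacterial genera). For an
#' additive matrix the tree's path-length matrix reproduces the input
#' exactly. Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with the deficit transferred to the adjacent
#' branch at the same node (standard practice); the number of clamped
#' branches is recorded in \code{attr(tree, "n_clamped")}.
#'
#' @param d a square symmetric matrix (or \code{dist}) with zero diagonal
#'   and at least 3 labelled taxa.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || nrow(d) < 3)
        stop("need a square matrix over at least 3 taxa")
    if (any(abs(d - t(d)) > 1e-8))
        stop("distance matrix must be symmetric")
    if (any(diag(d) != 0))
        stop("distance matrix must have a zero diagonal")
    if (any(d < 0))
        stop("distances must be non-negative")
    tr <- ape::nj(stats::as.dist(d))
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
        deficit <- -tr$edge.length[e]
        tr$edge.length[e] <- 0
        parent <- tr$edge[e, 1L]
        sib <- setdiff(which(tr$edge[, 1L] == parent |
                             tr$edge[, 2L] == parent), e)
        if (length(sib))
            tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
    }
    attr(tr, "n_clamped") <- length(neg)
    tr
}

# parent lookup and root of a phylo tree
.tree_parents <- function(tree) {
    parent <- integer(max(tree$edge))
    parent[tree$edge[, 2L]] <- tree$edge[, 1L]
    parent
}

.tree_root <- function(tree) {
    setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting a set of
#' tips \emph{and the root} (the classic rooted convention, so a single
#' taxon scores its root-to-tip path length). Computed as the union of the
#' root-to-tip edge paths of the selected taxa.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param taxaSet nonempty character vector of tip labels.
#' @return the PD value (same units as the branch lengths).
#' @examples
#' tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' faithPD(tr, c("A", "C"))   # 4
#' @export
faithPD <- function(tree, taxaSet) {
    taxaSet <- unique(taxaSet)
    if (length(taxaSet) == 0)
        stop("empty taxon set")
    missing <- setdiff(taxaSet, tree$tip.label)
    if (length(missing))
        stop("taxa not in tree: ", paste(missing, collapse = ", "))
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths")
    parent <- .tree_parents(tree)
    root <- .tree_root(tree)
    # edge index by child node
    edge_of <- integer(max(tree$edge))
    edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
    used <- logical(nrow(tree$edge))
    for (tip in match(taxaSet, tree$tip.label)) {
        node <- tip
        while (node != root) {
            e <- edge_of[node]
            if (used[e]) break
            used[e] <- TRUE
            node <- parent[node]
        }
    }
    sum(tree$edge.length[used])
}

#' Phylogenetic signal of a continuous trait (Pagel's lambda)
#'
#' Maximum-likelihood fit of a Brownian-motion model whose expected tip
#' covariance has its off-diagonal entries (shared root-to-ancestor path
#' lengths) multiplied by a scalar \eqn{\lambda \in [0, 1]}. \eqn{\lambda}
#' near 0 means the trait carries very little phylogenetic signal given the
#' tree; near 1, signal compatible with Brownian motion along the branches.
#' At each candidate \eqn{\lambda} the root state and the rate
#' \eqn{\sigma^2} are profiled analytically (GLS estimates), and
#' \eqn{\lambda} itself is optimized on [0, 1] by bounded scalar search
#' (tolerance 1e-6), with the boundary fits at 0 and 1 always evaluated so
#' a boundary maximum is never missed.
#'
#' @param tree a rooted \code{phylo} with branch lengths covering the trait
#'   names.
#' @param trait named numeric vector (names are tip labels); at least 4
#'   usable tips.
#' @return list of class \code{"lambdaFit"}: \code{lambda_hat},
#'   \code{loglik_at_hat}, \code{loglik_at_0}, \code{loglik_at_1},
#'   \code{sigma2_hat}, \code{root_state_hat}, \code{n_tips}.
#' @seealso \code{\link{prevalence}} for the trait most often tested;
#'   \code{\link{lambdaLRT}} for a likelihood-ratio test against
#'   \eqn{\lambda = 0}.
#' @export
pagelsLambda <- function(tree, trait) {
    trait <- trait[!is.na(trait)]
    keep <- intersect(tree$tip.label, names(trait))
    if (length(keep) < 4)
        stop("need at least 4 tips with trait values")
    tr <- ape::keep.tip(tree, keep)
    y <- trait[tr$tip.label]
    C <- ape::vcv(tr)
    offdiag <- C[upper.tri(C)]
    if (max(abs(offdiag)) < 1e-12 * max(diag(C)))
        stop("star tree: all shared path lengths are zero, ",
             "lambda is not identifiable")
    n <- length(y)
    profile_ll <- function(lambda) {
        Cl <- C * lambda
        diag(Cl) <- diag(C)
        ch <- tryCatch(chol(Cl), error = function(e) NULL)
        if (is.null(ch)) return(list(ll = -Inf))
        logdet <- 2 * sum(log(diag(ch)))
        Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
        Ciy <- backsolve(ch, forwardsolve(t(ch), y))
        mu <- sum(Ciy) / sum(Ci1)
        r <- y - mu
        Cir <- backsolve(ch, forwardsolve(t(ch), r))
        s2 <- sum(r * Cir) / n
        if (s2 <= 0) return(list(ll = -Inf))
        ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
        list(ll = ll, mu = mu, s2 = s2)
    }
    opt <- stats::optimize(function(l) profile_ll(l)$ll,
                           interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cands <- c(opt$maximum, 0, 1)
    lls <- vapply(cands, function(l) profile_ll(l)$ll, 0)
    best <- cands[which.max(lls)]
    fit <- profile_ll(best)
    out <- list(lambda_hat = best,
                loglik_at_hat = fit$ll,
                loglik_at_0 = lls[2L],
                loglik_at_1 = lls[3L],
                sigma2_hat = fit$s2,
                root_state_hat = fit$mu,
                n_tips = n)
    class(out) <- "lambdaFit"
    out
}

#' @export
print.lambdaFit <- function(x, ...) {
    cat(sprintf(
        "Pagel's lambda fit: lambda = %.4f (logLik %.3f; at 0: %.3f, at 1: %.3f)\n",
        x$lambda_hat, x$loglik_at_hat, x$loglik_at_0, x$loglik_at_1))
    cat(sprintf("sigma2 = %.4g, root state = %.4g, n = %d tips\n",
                x$sigma2_hat, x$root_state_hat, x$n_tips))
    invisible(x)
}

#' Likelihood-ratio test of lambda against zero
#'
#' Convenience chi-squared (1 df) comparison of the fitted lambda against
#' the no-signal model.
#'
#' @param fit a \code{lambdaFit} from \code{\link{pagelsLambda}}.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
lambdaLRT <- function(fit) {
    stat <- 2 * (fit$loglik_at_hat - fit$loglik_at_0)
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-taxon prevalence in a stratum
#'
#' Fraction of the stratum's samples in which each taxon is detected
#' (nonzero reads after filtering) -- the tip trait whose phylogenetic
#' signal is tested with \code{\link{pagelsLambda}}.
#'
#' @param x a \linkS4class{ReadMatrix}.
#' @param carrier,biotope stratum selectors (NULL pools over the factor).
#' @return named numeric vector over \code{taxa(x)}, values in [0, 1].
#' @export
prevalence <- function(x, carrier = NULL, biotope = NULL) {
    sel <- rep(TRUE, ncol(x))
    if (!is.null(carrier)) sel <- sel & carriers(x) == carrier
    if (!is.null(biotope)) sel <- sel & biotopes(x) == biotope
    if (!any(sel))
        stop("empty stratum")
    rowMeans(presenceMatrix(x)[, sel, drop = FALSE])
}
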