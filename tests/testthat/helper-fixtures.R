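# fixtures and independent oracles shared across test files

# small ReadMatrix from a samples-by-taxa presence/count specification:
# counts given taxa x samples
makeReadMatrix <- function(counts, carrier = "tick", biotope = "forest") {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    md <- data.frame(
        carrier = rep_len(carrier, ncol(counts)),
        biotope = rep_len(biotope, ncol(counts)),
        row.names = colnames(counts), stringsAsFactors = FALSE)
    ReadMatrix(counts, md)
}

# presence lists -> ReadMatrix (1 read per present taxon)
matrixFromSamples <- function(sample_taxa, carrier = "tick",
                              biotope = "forest") {
    taxa <- sort(unique(unlist(sample_taxa)))
    cts <- matrix(vapply(sample_taxa,
                         function(s) as.integer(taxa %in% s),
                         integer(length(taxa))),
                  nrow = length(taxa))
    rownames(cts) <- taxa
    colnames(cts) <- names(sample_taxa) %||%
        paste0("s", seq_along(sample_taxa))
    makeReadMatrix(cts, carrier, biotope)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force graph oracles (independent of igraph) -------------------

# exhaustive pairwise co-occurrence counts from a presence matrix
oracleCooccurrence <- function(P) {
    taxa <- rownames(P)
    out <- list()
    for (i in seq_along(taxa)) for (j in seq_along(taxa)) if (i < j) {
        w <- sum(P[i, ] & P[j, ])
        if (w > 0)
            out[[paste(taxa[i], taxa[j], sep = "|")]] <- w
    }
    out
}

# all-pairs betweenness by explicit shortest-path enumeration (adjacency
# matrix input, unweighted, undirected, unnormalized pair counting)
oracleBetweenness <- function(A) {
    n <- nrow(A)
    paths_between <- function(s, t) {
        # BFS distances from s
        dist <- rep(Inf, n); dist[s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (u in which(A[v, ] > 0))
                if (dist[u] == Inf) { dist[u] <- dist[v] + 1; queue <- c(queue, u) }
        }
        if (dist[t] == Inf) return(list())
        # enumerate all shortest s->t paths recursively (backwards)
        expand <- function(v) {
            if (v == s) return(list(s))
            preds <- which(A[v, ] > 0 & dist == dist[v] - 1)
            unlist(lapply(preds, function(p)
                lapply(expand(p), function(pp) c(pp, v))), recursive = FALSE)
        }
        expand(t)
    }
    bet <- rep(0, n)
    for (s in seq_len(n)) for (t in seq_len(n)) if (s < t) {
        ps <- paths_between(s, t)
        if (length(ps) == 0) next
        for (p in ps) {
            inner <- setdiff(p, c(s, t))
            bet[inner] <- bet[inner] + 1 / length(ps)
        }
    }
    stats::setNames(bet, rownames(A))
}

# local clustering coefficient by exhaustive triangle counting
oracleClustering <- function(A) {
    n <- nrow(A)
    cc <- rep(0, n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] > 0)
        k <- length(nb)
        if (k < 2) next
        tri <- 0
        for (i in seq_along(nb)) for (j in seq_along(nb)) if (i < j)
            tri <- tri + (A[nb[i], nb[j]] > 0)
        cc[v] <- 2 * tri / (k * (k - 1))
    }
    stats::setNames(cc, rownames(A))
}

# PageRank by direct linear solve of pr = d W pr + (1-d)/n,
# W column-stochastic over weights; dangling columns teleport uniformly
oraclePageRank <- function(W, damping = 0.85) {
    n <- nrow(W)
    colsum <- colSums(W)
    M <- matrix(1 / n, n, n)
    nz <- colsum > 0
    M[, nz] <- sweep(W[, nz, drop = FALSE], 2, colsum[nz], "/")
    pr <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
    stats::setNames(pr / sum(pr), rownames(W))
}

# weighted Newman modularity of a partition (adjacency matrix input)
oracleModularity <- function(A, membership) {
    m2 <- sum(A)                      # 2m for undirected stored symmetric
    if (m2 == 0) return(0)
    deg <- rowSums(A)
    Q <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
        if (membership[i] == membership[j])
            Q <- Q + A[i, j] - deg[i] * deg[j] / m2
    Q / m2
}

# enumerate all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
    out <- list()
    rec <- function(prefix, maxlab) {
        k <- length(prefix)
        if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
        for (lab in seq_len(maxlab + 1L))
            rec(c(prefix, lab), max(maxlab, lab))
    }
    rec(1L, 1L)
    out
}

# best-modularity partition by exhaustive search (n <= 8)
oracleBestPartition <- function(A) {
    parts <- allPartitions(nrow(A))
    qs <- vapply(parts, function(p) oracleModularity(A, p), 0)
    parts[[which.max(qs)]]
}

# partitions equal up to label renaming
samePartition <- function(a, b) {
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# union-of-root-paths Faith PD oracle using ape::nodepath
oracleFaithPD <- function(tree, taxaSet) {
    root <- length(tree$tip.label) + 1L
    edges <- c()
    for (tip in match(taxaSet, tree$tip.label)) {
        np <- ape::nodepath(tree, root, tip)
        for (i in seq_len(length(np) - 1))
            edges <- c(edges, paste(np[i], np[i + 1]))
    }
    edges <- unique(edges)
    key <- paste(tree$edge[, 1], tree$edge[, 2])
    sum(tree$edge.length[key %in% edges])
}
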