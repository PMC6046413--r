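test_that("edge weights count co-detections exactly", {
    x <- matrixFromSamples(list(S1 = c("a", "b"), S2 = c("a", "b"),
                                S3 = c("a", "c")))
    net <- buildCooccurrenceNetwork(x)
    g <- asGraph(net)
    w <- igraph::as_data_frame(g, "edges")
    key <- paste(pmin(w$from, w$to), pmax(w$from, w$to), sep = "|")
    got <- stats::setNames(w$weight, key)
    expect_equal(got[["a|b"]], 2)
    expect_equal(got[["a|c"]], 1)
    expect_false("b|c" %in% key)
    # weighted degree by hand summation: a=3, b=2, c=1
    expect_equal(weightedDegree(net),
                 c(a = 3, b = 2, c = 1))
    # handshake identity
    expect_equal(sum(weightedDegree(net)), 2 * sum(w$weight))
})

test_that("construction matches exhaustive pair enumeration on random data", {
    set.seed(21)
    for (rep in 1:10) {
        P <- matrix(runif(80) < 0.4, nrow = 8,
                    dimnames = list(letters[1:8], paste0("s", 1:10)))
        P[1, colSums(P) == 0] <- TRUE   # no fully empty sample
        x <- makeReadMatrix(P * 1L)
        net <- buildCooccurrenceNetwork(x)
        oracle <- oracleCooccurrence(P[rowSums(P) > 0, , drop = FALSE])
        ed <- igraph::as_data_frame(asGraph(net), "edges")
        got <- stats::setNames(ed$weight,
                               paste(pmin(ed$from, ed$to),
                                     pmax(ed$from, ed$to), sep = "|"))
        expect_equal(got[order(names(got))],
                     unlist(oracle)[order(names(oracle))])
        # edge weight bounded by each endpoint's occurrence count
        occ <- rowSums(P)
        for (k in names(got)) {
            pair <- strsplit(k, "|", fixed = TRUE)[[1]]
            expect_lte(got[[k]], min(occ[pair]))
        }
    }
})

test_that("a lone detection gives a single isolated node", {
    x <- matrixFromSamples(list(S1 = "a"))
    net <- buildCooccurrenceNetwork(x)
    expect_equal(igraph::vcount(asGraph(net)), 1)
    expect_equal(igraph::ecount(asGraph(net)), 0)
    expect_equal(unname(weightedDegree(net)), 0)
    # empty stratum errors
    expect_error(buildCooccurrenceNetwork(x, carrier = "vole"),
                 "empty stratum")
})

test_that("betweenness matches brute-force shortest-path enumeration", {
    # path a-b-c: only b lies between a pair
    x <- matrixFromSamples(list(S1 = c("a", "b"), S2 = c("b", "c")))
    net <- buildCooccurrenceNetwork(x)
    expect_equal(betweennessCentrality(net), c(a = 0, b = 1, c = 0))
    # complete graph: nobody is intermediate
    k4 <- matrixFromSamples(list(S1 = letters[1:4]))
    expect_equal(unname(betweennessCentrality(
        buildCooccurrenceNetwork(k4))), rep(0, 4))
    # 5-node star: center carries all C(4,2) = 6 pairs
    star <- matrixFromSamples(list(S1 = c("hub", "a"), S2 = c("hub", "b"),
                                   S3 = c("hub", "c"), S4 = c("hub", "d")))
    bnc <- betweennessCentrality(buildCooccurrenceNetwork(star))
    expect_equal(bnc[["hub"]], 6)
    # random graphs vs the enumeration oracle
    set.seed(31)
    for (rep in 1:5) {
        A <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
        pairs <- which(upper.tri(A), arr.ind = TRUE)
        on <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
        A[on] <- 1; A[on[, c(2, 1), drop = FALSE]] <- 1
        g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
        fake <- new("CooccurrenceNetwork", graph = g,
                    stratum = c(carrier = "x", biotope = "y"),
                    nodeMetrics = S4Vectors::DataFrame())
        expect_equal(betweennessCentrality(fake), oracleBetweenness(A),
                     tolerance = 1e-9)
    }
})

test_that("clustering coefficient equals exhaustive triangle counting", {
    tri <- matrixFromSamples(list(S1 = c("a", "b", "c")))
    expect_equal(unname(clusteringCoefficient(
        buildCooccurrenceNetwork(tri))), rep(1, 3))
    star <- matrixFromSamples(list(S1 = c("hub", "a"), S2 = c("hub", "b"),
                                   S3 = c("hub", "c")))
    cc <- clusteringCoefficient(buildCooccurrenceNetwork(star))
    expect_equal(cc[["hub"]], 0)
    # 4-cycle plus one chord, checked against the triangle-counting oracle
    A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))
    A[edges] <- 1; A[edges[, c(2, 1)]] <- 1
    g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
    fake <- new("CooccurrenceNetwork", graph = g,
                stratum = c(carrier = "x", biotope = "y"),
                nodeMetrics = S4Vectors::DataFrame())
    oracle <- oracleClustering(A)
    expect_equal(clusteringCoefficient(fake), oracle)
    expect_equal(unname(oracle[c("a", "c")]), c(2 / 3, 2 / 3))
    expect_equal(unname(oracle[c("b", "d")]), c(1, 1))
    # random graphs
    set.seed(41)
    for (rep in 1:5) {
        A <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
        pairs <- which(upper.tri(A), arr.ind = TRUE)
        on <- pairs[runif(nrow(pairs)) < 0.45, , drop = FALSE]
        A[on] <- 1; A[on[, c(2, 1), drop = FALSE]] <- 1
        g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
        fake@graph <- g
        expect_equal(clusteringCoefficient(fake), oracleClustering(A))
    }
})

test_that("PageRank matches a direct linear solve and conserves mass", {
    # two nodes, one edge: symmetry gives 0.5 each
    x2 <- matrixFromSamples(list(S1 = c("a", "b")))
    expect_equal(unname(pageRank(buildCooccurrenceNetwork(x2))),
                 c(0.5, 0.5))
    # 6-cycle: vertex-transitive, uniform 1/6
    cyc <- matrixFromSamples(lapply(1:6, function(i)
        c(letters[i], letters[i %% 6 + 1])))
    pr <- pageRank(buildCooccurrenceNetwork(cyc))
    expect_equal(unname(pr), rep(1 / 6, 6))
    # 3-node weighted path vs linear-system oracle
    x3 <- matrixFromSamples(list(S1 = c("a", "b"), S2 = c("a", "b"),
                                 S3 = c("b", "c")))
    net <- buildCooccurrenceNetwork(x3)
    W <- igraph::as_adjacency_matrix(asGraph(net), attr = "weight",
                                     sparse = FALSE)
    expect_equal(pageRank(net, damping = 0.85),
                 oraclePageRank(W, damping = 0.85), tolerance = 1e-9)
    # mass conservation on a bigger random instance with isolates
    set.seed(51)
    sim <- simulateReadMatrix(simConfig(
        n_genera = 40, n_packets = 5, packet_size_mean = 6,
        n_samples_per_group = c(tick.forest = 30), noise_genus_rate = 1,
        seed = 3))
    net <- buildCooccurrenceNetwork(sim$read_matrix)
    expect_equal(sum(pageRank(net)), 1, tolerance = 1e-9)
})

test_that("modularity communities recover planted structure", {
    # two 4-cliques joined by a single edge; oracle = exhaustive search
    A <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
    for (i in 1:4) for (j in 1:4) if (i != j) { A[i, j] <- 1; A[i + 4, j + 4] <- 1 }
    A[4, 5] <- A[5, 4] <- 1
    g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                             weighted = TRUE)
    net <- new("CooccurrenceNetwork", graph = g,
               stratum = c(carrier = "x", biotope = "y"),
               nodeMetrics = S4Vectors::DataFrame())
    got <- detectCommunities(net, seed = 1)
    best <- oracleBestPartition(A)
    expect_true(samePartition(unname(got[letters[1:8]]), best))
    expect_equal(length(unique(got)), 2)
    # labels ordered by size then name, starting at 0
    expect_equal(sort(unique(unname(got))), c(0L, 1L))
    # single clique stays one community
    k5 <- matrixFromSamples(list(S1 = letters[1:5]))
    expect_equal(length(unique(detectCommunities(
        buildCooccurrenceNetwork(k5), seed = 1))), 1)
})

test_that("returned partition beats the trivial partitions in modularity", {
    set.seed(61)
    sim <- simulateReadMatrix(simConfig(
        n_genera = 30, n_packets = 5, packet_size_mean = 5,
        n_samples_per_group = c(tick.forest = 40),
        packets_per_sample = c(1, 2), noise_genus_rate = 1, seed = 8))
    net <- buildCooccurrenceNetwork(sim$read_matrix)
    memb <- detectCommunities(net, seed = 2)
    A <- igraph::as_adjacency_matrix(asGraph(net), attr = "weight",
                                     sparse = FALSE)
    q <- oracleModularity(A, unname(memb[rownames(A)]))
    expect_gte(q, oracleModularity(A, seq_len(nrow(A))))   # singletons
    expect_gte(q, oracleModularity(A, rep(1, nrow(A))))    # one block
})

test_that("node metrics are invariant under taxon relabeling", {
    set.seed(71)
    sim <- simulateReadMatrix(simConfig(
        n_genera = 25, n_packets = 4, packet_size_mean = 5,
        n_samples_per_group = c(tick.forest = 25), seed = 5))
    x <- sim$read_matrix
    net1 <- buildCooccurrenceNetwork(x)
    perm <- sample(taxa(x))
    cts <- readCounts(x)[perm, , drop = FALSE]
    rownames(cts) <- taxa(x)   # same names, permuted structure
    net2 <- buildCooccurrenceNetwork(makeReadMatrix(cts))
    # map: taxon i of x plays the role of name taxa(x)[match(perm == ...)]
    remap <- stats::setNames(taxa(x), perm)
    for (metric in list(weightedDegree, betweennessCentrality,
                        clusteringCoefficient, pageRank)) {
        m1 <- metric(net1)
        m2 <- metric(net2)
        common <- intersect(names(m1), perm)
        expect_equal(unname(m1[common]),
                     unname(m2[remap[common]]), tolerance = 1e-12)
    }
})

test_that("power-law fitting flags degenerate input and separates
           exponential from power-law tails", {
    expect_error(fitPowerLaw(rep(5, 50)), "degenerate")
    expect_error(fitPowerLaw(1:5), "at least 10")
    set.seed(81)
    n <- 3000
    pl <- (1 - runif(n))^(-1 / 1.5)          # continuous, gamma 2.5, xmin 1
    ex <- rexp(n) + 1
    fit_pl <- fitPowerLaw(pl)
    fit_ex <- fitPowerLaw(ex)
    expect_lt(fit_pl$ks_distance, fit_ex$ks_distance)
    expect_equal(fit_pl$gamma, 2.5, tolerance = 0.15)
    expect_gt(fit_pl$gamma_regression, 1)
})
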