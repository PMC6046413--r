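test_that("noise-free one-packet samples contain exactly one packet", {
    cfg <- simConfig(n_genera = 20, n_packets = 4, packet_size_mean = 5,
                     packets_per_sample = c(1, 1), noise_genus_rate = 0,
                     n_samples_per_group = c(tick.forest = 30), seed = 3)
    sim <- simulateReadMatrix(cfg)
    P <- presenceMatrix(sim$read_matrix)
    for (s in seq_len(ncol(P))) {
        present <- rownames(P)[P[, s]]
        expect_length(present, 5)
        expect_equal(length(unique(sim$packet_assignment[present])), 1)
    }
    # cross-packet pairs never co-occur; same-packet pairs always do
    pa <- sim$packet_assignment
    co <- tcrossprod(P * 1)
    for (i in rownames(co)) for (j in colnames(co)) if (i < j) {
        if (is.na(pa[i]) || is.na(pa[j]) || pa[i] != pa[j])
            expect_equal(co[i, j], 0)
    }
})

test_that("identical seeds reproduce the simulation bit-exactly", {
    cfg <- simConfig(n_samples_per_group = c(tick.forest = 10,
                                             vole.forest = 10,
                                             tick.ecotone = 5,
                                             vole.ecotone = 5),
                     n_genera = 40, n_packets = 6, packet_size_mean = 5,
                     seed = 99)
    s1 <- simulateReadMatrix(cfg)
    s2 <- simulateReadMatrix(cfg)
    expect_identical(readCounts(s1$read_matrix),
                     readCounts(s2$read_matrix))
    expect_identical(s1$packet_assignment, s2$packet_assignment)
    expect_identical(writeNewick(s1$tree), writeNewick(s2$tree))
    s3 <- simulateReadMatrix(simConfig(n_samples_per_group =
        c(tick.forest = 10, vole.forest = 10, tick.ecotone = 5,
          vole.ecotone = 5), n_genera = 40, n_packets = 6,
        packet_size_mean = 5, seed = 100))
    expect_false(identical(readCounts(s1$read_matrix),
                           readCounts(s3$read_matrix)))
})

test_that("disjoint biotope pools give zero cross-biotope Sorensen", {
    cfg <- simConfig(n_genera = 60, n_packets = 8, packet_size_mean = 6,
                     biotope_overlap = 0, carrier_overlap = 1,
                     n_samples_per_group = c(tick.forest = 20,
                                             tick.ecotone = 20),
                     seed = 12)
    sim <- simulateReadMatrix(cfg)
    poolF <- sim$group_pools[["tick.forest"]]
    poolE <- sim$group_pools[["tick.ecotone"]]
    expect_equal(sorensen(poolF, poolE), 0)
    obsF <- stratumGenusSet(sim$read_matrix, biotope = "forest")
    obsE <- stratumGenusSet(sim$read_matrix, biotope = "ecotone")
    expect_equal(sorensen(obsF, obsE), 0)
})

test_that("every detected genus belongs to its group pool and the tree
           covers the genus universe", {
    cfg <- simConfig(n_genera = 50, n_packets = 6, packet_size_mean = 6,
                     n_samples_per_group = c(tick.forest = 15,
                                             vole.forest = 15),
                     seed = 8)
    sim <- simulateReadMatrix(cfg)
    x <- sim$read_matrix
    for (g in names(sim$group_pools)) {
        parts <- strsplit(g, ".", fixed = TRUE)[[1]]
        det <- stratumGenusSet(x, carrier = parts[1], biotope = parts[2])
        expect_true(all(det %in% sim$group_pools[[g]]))
    }
    expect_setequal(sim$tree$tip.label, taxa(x))
    # present genera always have at least 1 read (truncated NB)
    cts <- readCounts(x)
    expect_true(all(cts[cts > 0] >= 1))
})

test_that("mean per-sample richness approaches the packet model expectation", {
    cfg <- simConfig(n_genera = 100, n_packets = 10, packet_size_mean = 6,
                     packets_per_sample = c(1, 3), noise_genus_rate = 2,
                     n_samples_per_group = c(tick.forest = 400),
                     seed = 77)
    sim <- simulateReadMatrix(cfg)
    rich <- colSums(presenceMatrix(sim$read_matrix))
    # expectation: mean packets (2) x packet size (6) + noise rate (2)
    expect_equal(mean(rich), 2 * 6 + 2, tolerance = 0.06)
})

test_that("impossible packet configurations are rejected", {
    expect_error(simConfig(n_genera = 10, n_packets = 5,
                           packet_size_mean = 5),
                 "configuration error")
    expect_error(simConfig(biotope_overlap = 1.5), "biotope_overlap")
    expect_error(simConfig(n_samples_per_group = c(forest = 5)),
                 "carrier.biotope")
})

test_that("Yule trees have the requested size and reproduce under a seed", {
    t2 <- simulateYuleTree(2, seed = 1)
    expect_equal(length(t2$tip.label), 2)
    expect_equal(t2$Nnode, 1)
    t126 <- simulateYuleTree(126, seed = 4)
    expect_equal(length(t126$tip.label), 126)
    expect_equal(t126$Nnode, 125)        # bifurcating: n - 1 internal nodes
    expect_true(all(t126$edge.length > 0))
    expect_identical(writeNewick(simulateYuleTree(30, seed = 9)),
                     writeNewick(simulateYuleTree(30, seed = 9)))
    expect_error(simulateYuleTree(1), "at least 2")
})

test_that("lambda-scaled Brownian traits have the stated covariance
           structure", {
    tree <- simulateYuleTree(50, seed = 2)
    # lambda = 0: independent normals with variance sigma2 x tip depth
    depths <- ape::node.depth.edgelength(tree)[seq_len(50)]
    reps <- vapply(1:200, function(i)
        simulateBMTrait(tree, lambda_true = 0, sigma2 = 2, seed = i),
        numeric(50))
    emp_var <- apply(reps, 1, var)
    expect_equal(mean(emp_var / (2 * depths)), 1, tolerance = 0.1)
    off_cor <- cor(reps[1, ], reps[2, ])
    expect_lt(abs(off_cor), 0.2)
    # fixed seed reproduces the vector
    expect_identical(simulateBMTrait(tree, 0.5, seed = 11),
                     simulateBMTrait(tree, 0.5, seed = 11))
    noBL <- tree; noBL$edge.length <- NULL
    expect_error(simulateBMTrait(noBL, 1), "branch lengths")
})

test_that("simulation writes read matrix, tree and ground truth to disk", {
    dir <- tempfile()
    cfg <- simConfig(n_genera = 30, n_packets = 4, packet_size_mean = 6,
                     n_samples_per_group = c(tick.forest = 8,
                                             vole.forest = 8), seed = 21)
    sim <- simulateReadMatrix(cfg)
    writeSimulation(sim, dir)
    expect_true(file.exists(file.path(dir, "read_matrix.tsv")))
    back <- readReadMatrix(file.path(dir, "read_matrix.tsv"))
    expect_identical(readCounts(back), readCounts(sim$read_matrix))
    tr <- readNewick(file = file.path(dir, "tree.nwk"))
    expect_setequal(tr$tip.label, taxa(sim$read_matrix))
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
    expect_named(gt, c("packet_assignment", "group_pools"))
})
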