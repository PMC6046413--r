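#' Simulation configuration
#'
#' Parameters of the synthetic read-matrix generator. The defaults mirror
#' the study design the framework targets: two carriers (tick, vole) in two
#' biotopes (forest, ecotone) with 228/73/177/92 samples, 126 bacterial
#' genera organized in latent "packets" of co-occurring genera, a mean
#' per-sample genus richness of about 13.4, biotope-specific genus pools
#' with limited cross-biotope overlap, and negative-binomial read depths.
#'
#' @param n_genera number of genera in the universe.
#' @param n_samples_per_group named integer vector over
#'   \code{"carrier.biotope"} groups.
#' @param n_packets number of latent co-occurrence packets.
#' @param packet_size_mean mean genera per packet;
#'   \code{n_packets * packet_size_mean} must not exceed \code{n_genera}
#'   (genera left over become rare background taxa shared along the same
#'   overlap structure).
#' @param packets_per_sample integer range \code{c(min, max)}: each sample
#'   carries a uniform number of packets in this range.
#' @param noise_genus_rate expected (Poisson) number of extra non-packet
#'   genera per sample, drawn from the sample's group pool.
#' @param biotope_overlap fraction of packets (and background genera)
#'   shared between the two biotopes, in [0, 1].
#' @param carrier_overlap fraction of a biotope's packets shared between
#'   the two carriers, in [0, 1].
#' @param nb_mean,nb_dispersion negative-binomial read-count model for a
#'   present genus (mean mu and dispersion size; counts are truncated below
#'   at 1 so a present genus is always observable).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_genera = 126,
                      n_samples_per_group = c(tick.forest = 228,
                                              tick.ecotone = 73,
                                              vole.forest = 177,
                                              vole.ecotone = 92),
                      n_packets = 16,
                      packet_size_mean = 7.5,
                      packets_per_sample = c(1, 2),
                      noise_genus_rate = 2.2,
                      biotope_overlap = 0.25,
                      carrier_overlap = 0.6,
                      nb_mean = 610,
                      nb_dispersion = 0.5,
                      seed = 1) {
    stopifnot(n_genera >= 1, all(n_samples_per_group >= 1),
              n_packets >= 1, packet_size_mean > 0,
              length(packets_per_sample) == 2,
              packets_per_sample[1] >= 1,
              packets_per_sample[2] >= packets_per_sample[1],
              noise_genus_rate >= 0,
              biotope_overlap >= 0, biotope_overlap <= 1,
              carrier_overlap >= 0, carrier_overlap <= 1,
              nb_mean > 0, nb_dispersion > 0)
    if (round(n_packets * packet_size_mean) > n_genera)
        stop("configuration error: n_packets * packet_size_mean exceeds ",
             "n_genera; packets cannot be constructed")
    if (is.null(names(n_samples_per_group)) ||
        !all(grepl("\\.", names(n_samples_per_group))))
        stop("n_samples_per_group must be named 'carrier.biotope'")
    cfg <- as.list(environment())
    class(cfg) <- "simConfig"
    cfg
}

# size-safe sampling (sample() treats a scalar as 1:x)
.resample <- function(x, size) x[sample.int(length(x), size)]

# split items into (shared, onlyA, onlyB) with a given shared fraction
.split_overlap <- function(items, frac) {
    n <- length(items)
    n_sh <- round(frac * n)
    rest <- items[setdiff(seq_len(n), seq_len(n_sh))]
    nA <- ceiling(length(rest) / 2)
    list(shared = items[seq_len(n_sh)],
         onlyA = rest[seq_len(nA)],
         onlyB = rest[setdiff(seq_along(rest), seq_len(nA))])
}

#' Simulate a read matrix with planted co-occurrence structure
#'
#' Generates a \linkS4class{ReadMatrix} in which microorganisms circulate
#' together in latent packets. Genera are partitioned into packets; packets
#' (and leftover background genera) are allocated to carrier-by-biotope
#' group pools with the configured biotope and carrier overlaps. Each
#' sample draws a uniform number of packets from its group pool, marks all
#' their genera present, adds Poisson-distributed noise genera from the
#' same pool, and assigns each present genus a negative-binomial read
#' count truncated below at 1. Absent genera get 0 reads.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{read_matrix} (a
#'   \linkS4class{ReadMatrix}), \code{tree} (a Yule genus tree over the
#'   whole universe), \code{packet_assignment} (named integer vector, NA
#'   for background genera) and \code{group_pools} (list of genus sets per
#'   group) -- the ground truth every downstream stage can be checked
#'   against.
#' @export
simulateReadMatrix <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    genera <- sprintf("genus_%03d", seq_len(config$n_genera))
    n_in_packets <- round(config$n_packets * config$packet_size_mean)
    # deterministic near-equal packet sizes summing to n_in_packets
    base <- n_in_packets %/% config$n_packets
    sizes <- rep(base, config$n_packets)
    extra <- n_in_packets - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    shuffled <- sample(genera)
    packet_assignment <- rep(NA_integer_, config$n_genera)
    names(packet_assignment) <- genera
    idx <- 1L
    packets <- vector("list", config$n_packets)
    for (p in seq_len(config$n_packets)) {
        packets[[p]] <- shuffled[idx:(idx + sizes[p] - 1L)]
        packet_assignment[packets[[p]]] <- p
        idx <- idx + sizes[p]
    }
    background <- shuffled[idx:config$n_genera]
    if (idx > config$n_genera) background <- character()

    groups <- names(config$n_samples_per_group)
    parts <- strsplit(groups, ".", fixed = TRUE)
    carriers_g <- vapply(parts, `[[`, "", 1L)
    biotopes_g <- vapply(parts, `[[`, "", 2L)
    u_bio <- unique(biotopes_g)
    u_car <- unique(carriers_g)
    if (length(u_bio) > 2 || length(u_car) > 2)
        stop("the overlap model supports at most two carriers and two biotopes")

    # allocate packets to biotopes, then to carriers within a biotope
    pk_bio <- .split_overlap(seq_len(config$n_packets),
                             config$biotope_overlap)
    bg_bio <- .split_overlap(background, config$biotope_overlap)
    biotope_packets <- list()
    biotope_bg <- list()
    for (i in seq_along(u_bio)) {
        own <- if (i == 1L) pk_bio$onlyA else pk_bio$onlyB
        biotope_packets[[u_bio[i]]] <- c(pk_bio$shared, own)
        own_bg <- if (i == 1L) bg_bio$onlyA else bg_bio$onlyB
        biotope_bg[[u_bio[i]]] <- c(bg_bio$shared, own_bg)
    }
    if (length(u_bio) == 1L) {
        biotope_packets[[u_bio]] <- seq_len(config$n_packets)
        biotope_bg[[u_bio]] <- background
    }
    group_packets <- list()
    group_pools <- list()
    for (b in u_bio) {
        ca <- .split_overlap(biotope_packets[[b]], config$carrier_overlap)
        for (i in seq_along(u_car)) {
            g <- paste(u_car[i], b, sep = ".")
            if (!g %in% groups) next
            own <- if (i == 1L) ca$onlyA else ca$onlyB
            gp <- if (length(u_car) == 1L) biotope_packets[[b]]
                  else c(ca$shared, own)
            group_packets[[g]] <- gp
            group_pools[[g]] <- sort(c(unlist(packets[gp]),
                                       biotope_bg[[b]]))
        }
    }

    n_total <- sum(config$n_samples_per_group)
    cts <- matrix(0L, nrow = config$n_genera, ncol = n_total,
                  dimnames = list(genera, NULL))
    sample_ids <- character(n_total)
    md <- data.frame(carrier = character(n_total),
                     biotope = character(n_total),
                     sex = character(n_total),
                     stringsAsFactors = FALSE)
    col <- 0L
    for (gi in seq_along(groups)) {
        g <- groups[gi]
        pk_avail <- group_packets[[g]]
        pool <- group_pools[[g]]
        for (s in seq_len(config$n_samples_per_group[[g]])) {
            col <- col + 1L
            sample_ids[col] <- sprintf("%s_%03d", gsub(".", "_", g,
                                                       fixed = TRUE), s)
            k <- .resample(config$packets_per_sample[1]:
                           config$packets_per_sample[2], 1L)
            k <- min(k, length(pk_avail))
            drawn <- .resample(pk_avail, k)
            present <- unlist(packets[drawn])
            n_noise <- stats::rpois(1L, config$noise_genus_rate)
            candidates <- setdiff(pool, present)
            if (n_noise > 0 && length(candidates) > 0)
                present <- c(present,
                             .resample(candidates,
                                       min(n_noise, length(candidates))))
            reads <- pmax(1L, stats::rnbinom(length(present),
                                             mu = config$nb_mean,
                                             size = config$nb_dispersion))
            cts[present, col] <- as.integer(reads)
            md$carrier[col] <- carriers_g[gi]
            md$biotope[col] <- biotopes_g[gi]
            md$sex[col] <- sample(c("M", "F"), 1L)
        }
    }
    rownames(md) <- sample_ids
    colnames(cts) <- sample_ids
    rm <- ReadMatrix(cts, md, taxonRank = "genus")
    tree <- simulateYuleTree(config$n_genera, seed = config$seed,
                             tip_labels = genera)
    list(read_matrix = rm, tree = tree,
         packet_assignment = packet_assignment,
         group_pools = group_pools)
}

#' Simulate a pure-birth (Yule) genus tree
#'
#' Stand-in for a real genus phylogeny: only the tree shape and branch
#' lengths matter downstream (Faith's PD, Pagel's lambda).
#'
#' @param n_tips number of tips (at least 2).
#' @param seed RNG seed; identical seeds give identical Newick strings.
#' @param tip_labels optional tip labels (default \code{genus_001} ...).
#' @return a rooted binary \code{phylo} with positive branch lengths.
#' @export
simulateYuleTree <- function(n_tips, seed = 1, tip_labels = NULL) {
    if (n_tips < 2)
        stop("need at least 2 tips")
    set.seed(seed)
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$tip.label <- if (is.null(tip_labels))
        sprintf("genus_%03d", seq_len(n_tips)) else tip_labels
    tr
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait whose covariance is the tree's
#' Brownian-motion covariance (shared root-to-ancestor path lengths) with
#' the off-diagonal entries multiplied by \code{lambda_true} -- the
#' generative counterpart of \code{\link{pagelsLambda}}, used for
#' parameter-recovery checks. \code{lambda_true = 0} gives independent
#' normals with variance \code{sigma2} times each tip's depth.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param lambda_true signal strength in [0, 1].
#' @param sigma2 Brownian rate.
#' @param seed RNG seed.
#' @param root_state trait value at the root.
#' @return named numeric vector over the tips.
#' @export
simulateBMTrait <- function(tree, lambda_true, sigma2 = 1, seed = 1,
                            root_state = 0) {
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths")
    stopifnot(lambda_true >= 0, lambda_true <= 1, sigma2 > 0)
    C <- ape::vcv(tree)
    Cl <- C * lambda_true
    diag(Cl) <- diag(C)
    set.seed(seed)
    z <- stats::rnorm(nrow(Cl))
    L <- chol(sigma2 * Cl)
    stats::setNames(root_state + as.vector(t(L) %*% z), rownames(Cl))
}

#' Write a simulation to disk
#'
#' Serializes a \code{\link{simulateReadMatrix}} result: the read matrix as
#' TSV, the genus tree as Newick, and the ground truth (packet assignment
#' and group pools) as JSON.
#'
#' @param sim output of \code{\link{simulateReadMatrix}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeReadMatrix(sim$read_matrix, file.path(dir, "read_matrix.tsv"))
    writeNewick(sim$tree, file.path(dir, "tree.nwk"))
    jsonlite::write_json(
        list(packet_assignment = as.list(sim$packet_assignment),
             group_pools = sim$group_pools),
        file.path(dir, "ground_truth.json"), auto_unbox = TRUE,
        null = "null")
    invisible(dir)
}
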