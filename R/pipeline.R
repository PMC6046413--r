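#' Run the full analysis pipeline
#'
#' Orchestrates the whole framework from a single configuration: read (or
#' accept) a sample-by-genus table, optionally merge PCR replicates, apply
#' the three filtering rules, then per carrier-by-biotope stratum build the
#' genus co-occurrence network with all node indexes and communities, fit
#' the power law of weighted degrees, estimate the phylogenetic signal
#' (Pagel's lambda) of prevalence and of the network indexes on the genus
#' tree, score host specificity per biotope, build the individual-carrier
#' similarity networks with their communities, and summarize community
#' composition, Sorensen similarities, shared/exclusive genera and the
#' concentration of phylogenetic diversity. Every output is a plain-text
#' table/JSON file in \code{outDir}, and a manifest records parameters and
#' seeds so a rerun with the same config is byte-identical.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{read_table / replicate_b}{path(s) to the count table(s); or
#'       pass a \linkS4class{ReadMatrix} via \code{read_matrix}.}
#'     \item{tree}{path to a Newick genus tree, or a \code{phylo} object;
#'       or \code{distance_matrix}, a square TSV from which a
#'       neighbor-joining tree is built.}
#'     \item{percentile}{low-read cutoff percentile (default 10).}
#'     \item{assigned}{optional vector/file of genus-assigned taxa.}
#'     \item{seed}{community-detection seed (default 1).}
#'     \item{resolution}{Louvain resolution (default 1).}
#'     \item{damping}{PageRank damping (default 0.85).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return the output directory, invisibly; side effect: files written.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(
        list(percentile = 10, seed = 1, resolution = 1, damping = 0.85,
             out_dir = "micronet_out", assigned = NULL, iterate = FALSE),
        config)
    for (key in c("read_table", "replicate_b", "tree", "distance_matrix"))
        if (is.character(cfg[[key]]) && !file.exists(cfg[[key]]))
            stop("stage input: file not found for '", key, "': ", cfg[[key]])

    outDir <- cfg$out_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log_lines <- character()
    say <- function(...) {
        line <- sprintf(...)
        log_lines <<- c(log_lines, line)
        message(line)
    }

    ## --- stage: sample_io -------------------------------------------------
    x <- if (!is.null(cfg$read_matrix)) cfg$read_matrix
         else tryCatch(readReadMatrix(cfg$read_table),
                       error = function(e)
                           stop("stage sample_io: ", conditionMessage(e)))
    if (!is.null(cfg$replicate_b)) {
        repB <- readReadMatrix(cfg$replicate_b)
        x <- mergeReplicates(x, repB)
        say("merged PCR replicates")
    }
    say("loaded %d taxa x %d samples", nrow(x), ncol(x))

    ## --- stage: filtering -------------------------------------------------
    assigned <- cfg$assigned
    if (is.character(assigned) && length(assigned) == 1L &&
        file.exists(assigned))
        assigned <- readLines(assigned)
    x <- tryCatch(applyFilters(x, assigned = assigned,
                               percentile = cfg$percentile,
                               iterate = isTRUE(cfg$iterate)),
                  error = function(e)
                      stop("stage filtering: ", conditionMessage(e)))
    writeReadMatrix(x, file.path(outDir, "filtered_matrix.tsv"))
    jsonlite::write_json(.report_for_json(filterReport(x)),
                         file.path(outDir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    say("filtering done (%d taxa retained)", nrow(x))

    ## --- stage: tree ------------------------------------------------------
    tree <- cfg$tree
    if (is.character(tree)) tree <- readNewick(file = tree)
    if (is.null(tree) && !is.null(cfg$distance_matrix)) {
        d <- as.matrix(utils::read.table(cfg$distance_matrix, header = TRUE,
                                         sep = "\t", row.names = 1L,
                                         check.names = FALSE))
        tree <- njTree(d)
    }
    if (is.null(tree))
        stop("stage phylo: no tree or distance matrix supplied")

    ## --- stage: taxon networks per stratum --------------------------------
    strata <- unique(data.frame(carrier = carriers(x),
                                biotope = biotopes(x)))
    strata <- strata[order(strata$carrier, strata$biotope), ]
    networks <- list()
    lambda_rows <- list()
    powerlaw <- list()
    for (i in seq_len(nrow(strata))) {
        ca <- strata$carrier[i]; bi <- strata$biotope[i]
        key <- paste(ca, bi, sep = ".")
        net <- buildCooccurrenceNetwork(x, carrier = ca, biotope = bi)
        net <- computeNodeMetrics(net, damping = cfg$damping,
                                  resolution = cfg$resolution,
                                  seed = cfg$seed)
        networks[[key]] <- net
        exportNetwork(net,
                      graphml = file.path(outDir,
                                          paste0("network_", key, ".graphml")),
                      tsv = file.path(outDir,
                                      paste0("node_metrics_", key, ".tsv")))
        wd <- weightedDegree(net)
        powerlaw[[key]] <- tryCatch(fitPowerLaw(wd),
                                    error = function(e)
                                        list(error = conditionMessage(e)))
        # phylogenetic signal of prevalence and of the node indexes
        nm <- nodeMetrics(net)
        traits <- c(list(prevalence = prevalence(x, carrier = ca,
                                                 biotope = bi)),
                    lapply(stats::setNames(c("WD", "BNC", "CC", "PR"),
                                           c("WD", "BNC", "CC", "PR")),
                           function(col) stats::setNames(nm[[col]],
                                                         rownames(nm))))
        for (tn in names(traits)) {
            fit <- tryCatch(pagelsLambda(tree, traits[[tn]]),
                            error = function(e) NULL)
            if (!is.null(fit))
                lambda_rows[[paste(key, tn)]] <-
                    data.frame(stratum = key, trait = tn,
                               lambda = fit$lambda_hat,
                               loglik = fit$loglik_at_hat)
        }
        say("stratum %s: %d nodes, %d links", key,
            igraph::vcount(asGraph(net)), igraph::ecount(asGraph(net)))
    }
    lambda_tab <- do.call(rbind, lambda_rows)
    if (is.null(lambda_tab))
        lambda_tab <- data.frame(stratum = character(), trait = character(),
                                 lambda = numeric(), loglik = numeric())
    utils::write.table(lambda_tab,
                       file.path(outDir, "phylo_signal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(powerlaw, file.path(outDir, "power_law.json"),
                         auto_unbox = TRUE, digits = NA)

    ## --- stage: specificity per biotope -----------------------------------
    two_carriers <- length(unique(carriers(x))) == 2
    if (two_carriers) {
        for (bi in unique(biotopes(x))) {
            tab <- specificityTable(x, biotope = bi)
            utils::write.table(tab,
                               file.path(outDir,
                                         paste0("specificity_", bi, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
        say("specificity tables written")
    }

    ## --- stage: carrier networks + community stats ------------------------
    carrier_nets <- list()
    summaries <- list()
    concentration <- list()
    for (bi in unique(biotopes(x))) {
        cn <- buildCarrierNetwork(x, biotope = bi)
        cn <- detectCarrierCommunities(cn, resolution = cfg$resolution,
                                       seed = cfg$seed)
        carrier_nets[[bi]] <- cn
        igraph::write_graph(asGraph(cn),
                            file.path(outDir,
                                      paste0("carrier_network_", bi,
                                             ".graphml")),
                            format = "graphml")
        smry <- summarizeCommunities(cn, x, tree)
        summaries[[bi]] <- smry
        utils::write.table(smry,
                           file.path(outDir,
                                     paste0("carrier_communities_", bi,
                                            ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (nrow(smry) >= 2)
            concentration[[bi]] <- pdConcentration(smry, tree = tree,
                                                   x = x, net = cn)
        say("carrier network %s: %d communities", bi,
            nrow(smry))
    }
    report <- list(sorensen = sorensenMatrix(x),
                   pd_concentration = concentration)
    if (two_carriers)
        report$shared_exclusive <-
            sharedExclusive(x)[c("n_shared", "pct_shared")]
    jsonlite::write_json(report,
                         file.path(outDir, "community_report.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

    ## --- manifest ---------------------------------------------------------
    manifest <- list(
        package_version = as.character(utils::packageVersion("micronet")),
        parameters = cfg[c("percentile", "seed", "resolution", "damping",
                           "iterate")],
        strata_networks = names(networks),
        carrier_networks = names(carrier_nets),
        outputs = sort(list.files(outDir)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(outDir, "run_log.txt"))
    invisible(outDir)
}

# filter report entries with long vectors trimmed for JSON
.report_for_json <- function(report) {
    lapply(report, function(entry) {
        if (!is.null(entry$per_taxon_cutoff))
            entry$per_taxon_cutoff <- as.list(entry$per_taxon_cutoff)
        entry
    })
}
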