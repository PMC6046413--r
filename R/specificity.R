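#' Log transform of mean read counts
#'
#' The host-specificity score works on \code{log10(0.1 + mean reads)}, a
#' transform that keeps zero-mean genera finite (a mean of 0 maps to -1)
#' while spreading the heavy right tail of read counts.
#'
#' @param meanReads non-negative numeric vector.
#' @return \code{log10(0.1 + meanReads)}.
#' @export
logReads <- function(meanReads) {
    if (any(meanReads < 0))
        stop("mean reads must be non-negative")
    log10(0.1 + meanReads)
}

#' Host-specificity table for one biotope
#'
#' Scores each genus's association with one carrier versus the other
#' within a biotope by contrasting read abundance between carriers against
#' the genus's position in the biotope's co-occurrence network. For each
#' genus: the mean reads per carrier (over \emph{all} of that carrier's
#' samples in the biotope, zeros included, unless
#' \code{positiveOnly = TRUE}), the log score
#' \deqn{\log_{10}(0.1 + \bar r_{carrierA}) - \log_{10}(0.1 + \bar r_{carrierB})}
#' (positive = associated to \code{carrierA}), the raw ratio of summed
#' reads (\code{Inf} when the denominator is 0 and the numerator positive;
#' \code{NaN} when both are 0), and the genus's weighted degree in the
#' biotope network. Genera with a high |log score| and high ratio are the
#' host-specific ones; intermediate values indicate circulation between
#' both carriers. Records are ranked by decreasing |log score|.
#'
#' @param x a filtered \linkS4class{ReadMatrix} with exactly two carriers
#'   present in \code{biotope}.
#' @param biotope the biotope to score.
#' @param carrierA,carrierB the carrier pair; defaults to the two carriers
#'   found in the biotope (sorted), with \code{carrierA} in the numerator.
#' @param network optional \linkS4class{CooccurrenceNetwork} supplying the
#'   WD column; by default the biotope-pooled network (both carriers) is
#'   built internally. Genera absent from the network get WD 0.
#' @param positiveOnly average only over samples where the genus is
#'   detected.
#' @return \code{data.frame} with columns \code{genus}, \code{biotope},
#'   \code{mean_reads_<carrierA>}, \code{mean_reads_<carrierB>},
#'   \code{log_score}, \code{raw_ratio}, \code{wd}.
#' @export
specificityTable <- function(x, biotope, carrierA = NULL, carrierB = NULL,
                             network = NULL, positiveOnly = FALSE) {
    sel <- biotopes(x) == biotope
    if (!any(sel))
        stop("no samples in biotope ", biotope)
    carr <- carriers(x)[sel]
    found <- sort(unique(carr))
    if (is.null(carrierA) || is.null(carrierB)) {
        if (length(found) != 2)
            stop("biotope ", biotope, " does not hold exactly two ",
                 "carriers (found: ", paste(found, collapse = ", "), ")")
        carrierA <- carrierA %||% found[2L]  # voles/ticks convention: later
        carrierB <- carrierB %||% setdiff(found, carrierA)[1L]
    }
    for (cc in c(carrierA, carrierB))
        if (!cc %in% found)
            stop("carrier ", cc, " has no samples in biotope ", biotope)
    cts <- readCounts(x)[, sel, drop = FALSE]
    meanfun <- function(sub) {
        if (!positiveOnly) rowMeans(sub)
        else apply(sub, 1L, function(v)
            if (any(v > 0)) mean(v[v > 0]) else 0)
    }
    mA <- meanfun(cts[, carr == carrierA, drop = FALSE])
    mB <- meanfun(cts[, carr == carrierB, drop = FALSE])
    sA <- rowSums(cts[, carr == carrierA, drop = FALSE])
    sB <- rowSums(cts[, carr == carrierB, drop = FALSE])
    if (is.null(network))
        network <- buildCooccurrenceNetwork(x, carrier = NULL,
                                            biotope = biotope)
    wd_net <- weightedDegree(network)
    wd <- stats::setNames(rep(0, nrow(cts)), rownames(cts))
    hit <- intersect(names(wd_net), names(wd))
    wd[hit] <- wd_net[hit]
    out <- data.frame(genus = rownames(cts), biotope = biotope,
                      mA = mA, mB = mB,
                      log_score = logReads(mA) - logReads(mB),
                      raw_ratio = sA / sB,
                      wd = wd, row.names = NULL,
                      stringsAsFactors = FALSE)
    names(out)[3:4] <- paste0("mean_reads_", c(carrierA, carrierB))
    out[order(-abs(out$log_score), out$genus), , drop = FALSE]
}
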