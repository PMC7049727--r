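#' Overlap summary between a cluster and a feature track
#'
#' Computes the three per-cluster summary statistics for the overlaps
#' between a genomic feature track and a cluster of bins:
#' \describe{
#'   \item{size}{`sum_i |site_i intersect cl| / bp_cl` — the proportion of
#'     the cluster covered by the feature (can exceed 1 only when track
#'     intervals overlap one another, since overlaps are summed per site
#'     without merging).}
#'   \item{intensity}{`sum_i |site_i intersect cl| * I_i / bp_cl` — the
#'     average overlapping signal intensity per bp.}
#'   \item{count}{number of sites with a non-empty intersection with the
#'     cluster.}
#' }
#'
#' @param cluster [GenomicRanges::GRanges] of the cluster's bins.
#' @param track [GenomicRanges::GRanges] of feature sites, with an
#'   intensity metadata column for the intensity metric.
#' @param metric `"size"`, `"intensity"` or `"count"`.
#' @param intensityCol metadata column holding `I_i` (default
#'   `"signalValue"`, falling back to `"score"`).
#' @return a one-row data.frame with `bpCl`, `value` and `metric`.
#' @export
overlapSummary <- function(cluster, track,
                           metric = c("size", "intensity", "count"),
                           intensityCol = "signalValue") {
    metric <- match.arg(metric)
    bpCl <- sum(GenomicRanges::width(cluster))
    hits <- GenomicRanges::findOverlaps(track, cluster, ignore.strand = TRUE)
    ov <- GenomicRanges::pintersect(
        track[S4Vectors::queryHits(hits)],
        cluster[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE
    )
    w <- GenomicRanges::width(ov)
    value <- switch(metric,
        size = sum(w) / bpCl,
        intensity = {
            ii <- trackIntensity(track, intensityCol)
            sum(w * ii[S4Vectors::queryHits(hits)]) / bpCl
        },
        count = length(unique(S4Vectors::queryHits(hits)))
    )
    data.frame(bpCl = bpCl, value = value, metric = metric)
}

#' @noRd
trackIntensity <- function(track, intensityCol = "signalValue") {
    mc <- S4Vectors::mcols(track)
    col <- if (intensityCol %in% names(mc)) {
        intensityCol
    } else if ("score" %in% names(mc)) {
        "score"
    } else {
        stop("track has no '", intensityCol,
            "' (or 'score') intensity column")
    }
    ii <- mc[[col]]
    if (anyNA(ii)) stop("track intensities contain NA")
    as.numeric(ii)
}

# Per-bin overlap values, vectorized over all bins of the chromosome.
#' @noRd
perLocusOverlap <- function(bins, track,
                            metric = c("size", "intensity", "count"),
                            intensityCol = "signalValue") {
    metric <- match.arg(metric)
    n <- length(bins)
    hits <- GenomicRanges::findOverlaps(track, bins, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    out <- numeric(n)
    if (!length(q)) return(out)
    if (metric == "count") {
        tab <- table(s)
        out[as.integer(names(tab))] <- as.integer(tab)
        return(out)
    }
    w <- GenomicRanges::width(
        GenomicRanges::pintersect(track[q], bins[s], ignore.strand = TRUE)
    )
    contrib <- if (metric == "size") {
        w
    } else {
        w * trackIntensity(track, intensityCol)[q]
    }
    agg <- tapply(contrib, s, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out / GenomicRanges::width(bins)
}

#' Per-locus feature enrichment along nestedness
#'
#' For the enrichment analysis the "clusters" are individual loci: each
#' locus gets its overlap value under the chosen metric, its per-locus
#' nestedness, and the feature enrichment
#' `FE_i = x_i / mean(x over loci of the same top enclave)` — the relative
#' enrichment as one descends from top enclaves towards the tree leaves.
#' Loci outside every top enclave, and loci of top enclaves whose mean
#' overlap is zero, are reported with `FE = NA` and excluded from trends.
#'
#' @param tree an [EnclaveTree].
#' @param labels its [EnclaveLabels].
#' @param ns result of [nestedness()] for the same tree/labels.
#' @param bins bin table of the contact map the tree was built on.
#' @param track feature track ([GenomicRanges::GRanges]).
#' @param metric overlap metric, see [overlapSummary()].
#' @param intensityCol intensity column for the intensity metric.
#' @return data.frame with `locus`, `ns`, `value`, `topEnclave`, `fe`.
#' @export
featureEnrichment <- function(tree, labels, ns, bins, track,
                              metric = c("count", "size", "intensity"),
                              intensityCol = "signalValue") {
    metric <- match.arg(metric)
    x <- perLocusOverlap(bins, track, metric, intensityCol)
    topOf <- rep(NA_character_, tree@nBins)
    for (id in labels@top) {
        topOf[tree@nodes[[id]]$loci] <- id
    }
    fe <- rep(NA_real_, tree@nBins)
    for (id in unique(stats::na.omit(topOf))) {
        sel <- which(topOf == id)
        m <- mean(x[sel])
        if (m > 0) fe[sel] <- x[sel] / m
    }
    data.frame(
        locus = seq_len(tree@nBins),
        ns = ns$perLocus$ns,
        value = x,
        topEnclave = topOf,
        fe = fe,
        stringsAsFactors = FALSE
    )
}

#' Exact Poisson rate-ratio test
#'
#' Two-sided exact test of an observed count against the count expected
#' from a genome-wide rate over the observed exposure, as used to test
#' whether the frequency of feature overlaps among a set of loci deviates
#' from the genome-wide frequency.
#'
#' @param observed observed count of overlaps.
#' @param exposure exposure of the observed count (bp or number of loci).
#' @param expectedRate expected genome-wide rate per unit of exposure.
#' @return list with `rateRatio`, `p` and `expected`. A zero expected rate
#'   with a non-zero observed count is degenerate-significant (`p = 0`,
#'   flagged with `degenerate = TRUE`).
#' @export
poissonRatioTest <- function(observed, exposure, expectedRate) {
    stopifnot(exposure > 0, expectedRate >= 0)
    expected <- expectedRate * exposure
    if (expectedRate == 0) {
        return(list(
            rateRatio = if (observed > 0) Inf else NaN,
            p = if (observed > 0) 0 else 1,
            expected = 0,
            degenerate = TRUE
        ))
    }
    ht <- stats::poisson.test(round(observed), T = exposure, r = expectedRate)
    list(
        rateRatio = (observed / exposure) / expectedRate,
        p = ht$p.value,
        expected = expected,
        degenerate = FALSE
    )
}

#' Poisson enrichment tests across nestedness strata
#'
#' Bins loci into nestedness strata, tests each stratum's overlap-count
#' frequency against the chromosome-wide rate with [poissonRatioTest()],
#' and adjusts the p-values with Benjamini-Hochberg FDR.
#'
#' @param fe result of [featureEnrichment()] (count metric).
#' @param breaks stratum boundaries on the NS scale.
#' @return data.frame with one row per non-empty stratum: `stratum`,
#'   `nLoci`, `observed`, `expected`, `rateRatio`, `p`, `padj`.
#' @export
nestednessEnrichmentTests <- function(fe, breaks = seq(0, 1, by = 0.2)) {
    ok <- !is.na(fe$ns) & !is.na(fe$value)
    dat <- fe[ok, ]
    rate <- sum(dat$value) / nrow(dat)
    stratum <- cut(dat$ns, breaks = breaks, include.lowest = TRUE)
    rows <- lapply(levels(stratum), function(s) {
        sel <- stratum == s
        if (!any(sel)) return(NULL)
        tst <- poissonRatioTest(sum(dat$value[sel]), sum(sel), rate)
        data.frame(
            stratum = s, nLoci = sum(sel), observed = sum(dat$value[sel]),
            expected = tst$expected, rateRatio = tst$rateRatio, p = tst$p
        )
    })
    out <- do.call(rbind, rows)
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out
}

#' Significance threshold for feature-enrichment values
#'
#' The non-parametric cut-off for "extreme" FE values relative to a null FE
#' distribution (from tree-matched random clusterings):
#' `threshold = 75th percentile + 2 * IQR`. Values strictly above the
#' threshold are flagged significant.
#'
#' @param nullFe numeric vector of null FE values.
#' @return the threshold (a single number).
#' @export
feSignificanceThreshold <- function(nullFe) {
    nullFe <- nullFe[!is.na(nullFe)]
    if (length(nullFe) < 20) {
        warning("null FE sample has fewer than 20 values; ",
            "threshold is unstable")
    }
    unname(stats::quantile(nullFe, 0.75)) + 2 * stats::IQR(nullFe)
}

#' DNA-loop integration by a flat enclave clustering
#'
#' A loop is integrated when both of its anchor sites fall in the same
#' single enclave. An anchor overlapping bins of several enclaves is
#' assigned to the enclave with the largest bp overlap (ties to the
#' enclave whose overlapping bins start earlier); anchors overlapping no
#' enclave bin (or only catch-all loci) are unassigned and their loop is
#' not integrated.
#'
#' @param loops loop anchors as a [S4Vectors::Pairs] of two GRanges (see
#'   [readLoops()]).
#' @param clustering a [FlatClustering] (e.g. from [enclaveClustering()]).
#' @param bins bin table aligned with the clustering.
#' @param unassignedLabel catch-all label to exclude from enclaves.
#' @return list with `percent` (100 * integrated / total) and `perLoop`
#'   (data.frame: `loop`, `anchor1`, `anchor2`, `integrated`).
#' @export
loopIntegration <- function(loops, clustering, bins,
                            unassignedLabel = "unclustered") {
    a1 <- S4Vectors::first(loops)
    a2 <- S4Vectors::second(loops)
    assignAnchor <- function(anchors) {
        lab <- clustering@assignment[bins$binId]
        hits <- GenomicRanges::findOverlaps(anchors, bins,
            ignore.strand = TRUE)
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        if (!length(q)) return(rep(NA_character_, length(anchors)))
        w <- GenomicRanges::width(GenomicRanges::pintersect(
            anchors[q], bins[s], ignore.strand = TRUE
        ))
        df <- data.frame(
            q = q, lab = lab[s], w = w,
            binStart = GenomicRanges::start(bins)[s]
        )
        df <- df[df$lab != unassignedLabel, , drop = FALSE]
        out <- rep(NA_character_, length(anchors))
        if (!nrow(df)) return(out)
        # total overlap and earliest overlapping bin per (anchor, enclave)
        aggW <- stats::aggregate(df$w, by = list(q = df$q, lab = df$lab), sum)
        aggS <- stats::aggregate(df$binStart,
            by = list(q = df$q, lab = df$lab), min)
        m <- merge(aggW, aggS, by = c("q", "lab"))
        names(m) <- c("q", "lab", "w", "minStart")
        m <- m[order(m$q, -m$w, m$minStart), ]
        best <- m[!duplicated(m$q), ]
        out[best$q] <- best$lab
        out
    }
    l1 <- assignAnchor(a1)
    l2 <- assignAnchor(a2)
    integrated <- !is.na(l1) & !is.na(l2) & l1 == l2
    list(
        percent = 100 * sum(integrated) / length(integrated),
        perLoop = data.frame(
            loop = seq_along(integrated),
            anchor1 = l1, anchor2 = l2, integrated = integrated,
            stringsAsFactors = FALSE
        )
    )
}
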