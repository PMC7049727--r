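#' Nestedness of partition-tree nodes and loci
#'
#' Nestedness (NS) places every node of the partition tree on a common
#' `[0, 1]` depth scale anchored at the topologically invariant landmarks:
#' 0 at top enclaves, 0.5 at bottom enclaves and 1 at leaves, with linear
#' interpolation in between based on root distance `D` (number of branches
#' from the root).
#'
#' For a node strictly between its top enclave and the bottom enclaves,
#' `NS = 0.5 * (D - minD) / ((maxD - minD) + 1)`, where `minD` is the root
#' distance of the closest top enclave above and `maxD` that of the
#' furthest bottom enclave below; the `+ 1` in the denominator keeps these
#' values strictly below 0.5. For a node strictly between a bottom enclave
#' and its leaf, `NS = 0.5 * (D - minD) / (maxD - minD) + 0.5`, with `minD`
#' the closest bottom enclave above and `maxD` the furthest descendant
#' leaf.
#'
#' Nodes above all top enclaves (the pure-split region, including the root)
#' carry no NS of their own; loci whose deepest containing node lies there
#' get a per-locus NS of 0. A node below a top enclave with no bottom
#' enclave among its descendants has undefined NS and is reported as such
#' (segment `"undefined"`).
#'
#' The per-locus NS is the NS of the most nested (deepest) node containing
#' the locus.
#'
#' @param tree an [EnclaveTree].
#' @param labels the [EnclaveLabels] of `tree` (computed if missing).
#' @return a list with `perNode` (data.frame: `id`, `rootDistance`,
#'   `segment`, `ns`) and `perLocus` (data.frame: `locus`, `nodeId`, `ns`).
#' @export
nestedness <- function(tree, labels = labelEnclaves(tree)) {
    nodes <- tree@nodes
    ids <- names(nodes)
    D <- vapply(nodes, function(nd) nd$rootDistance, integer(1))
    parent <- vapply(nodes, function(nd) nd$parent, character(1))
    depthOrder <- ids[order(D)]

    inTop <- ids %in% labels@top
    inBottom <- ids %in% labels@bottom
    inLeaf <- ids %in% labels@leaves
    names(inTop) <- names(inBottom) <- names(inLeaf) <- ids

    # nearest labelled ancestor distances (strictly above), top-down
    topAbove <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    bottomAbove <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    for (id in depthOrder) {
        p <- parent[[id]]
        if (is.na(p)) next
        topAbove[[id]] <- if (inTop[[p]]) D[[p]] else topAbove[[p]]
        bottomAbove[[id]] <- if (inBottom[[p]]) D[[p]] else bottomAbove[[p]]
    }
    # furthest labelled descendant distances (strictly below), bottom-up
    maxOf <- function(v) if (length(v) && any(!is.na(v))) {
        max(v, na.rm = TRUE)
    } else {
        NA_integer_
    }
    bottomBelow <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    leafBelow <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    for (id in rev(depthOrder)) {
        kids <- nodes[[id]]$children
        vb <- vapply(kids, function(k) {
            if (inBottom[[k]]) D[[k]] else bottomBelow[[k]]
        }, integer(1))
        vl <- vapply(kids, function(k) {
            if (inLeaf[[k]]) D[[k]] else leafBelow[[k]]
        }, integer(1))
        bottomBelow[[id]] <- maxOf(vb)
        leafBelow[[id]] <- maxOf(vl)
    }

    ns <- rep(NA_real_, length(ids))
    segment <- character(length(ids))
    for (i in seq_along(ids)) {
        id <- ids[i]
        if (inTop[[id]]) {
            ns[i] <- 0; segment[i] <- "top"
        } else if (inBottom[[id]]) {
            ns[i] <- 0.5; segment[i] <- "bottom"
        } else if (inLeaf[[id]]) {
            ns[i] <- 1; segment[i] <- "leaf"
        } else if (!is.na(bottomAbove[[id]])) {
            minD <- bottomAbove[[id]]
            maxD <- leafBelow[[id]]
            if (is.na(maxD)) {
                segment[i] <- "undefined"
            } else {
                ns[i] <- 0.5 * (D[[id]] - minD) / (maxD - minD) + 0.5
                segment[i] <- "lower"
            }
        } else if (!is.na(topAbove[[id]])) {
            minD <- topAbove[[id]]
            maxD <- bottomBelow[[id]]
            if (is.na(maxD)) {
                segment[i] <- "undefined"
            } else {
                ns[i] <- 0.5 * (D[[id]] - minD) / ((maxD - minD) + 1)
                segment[i] <- "upper"
            }
        } else {
            segment[i] <- "above_top"
        }
    }
    perNode <- data.frame(
        id = ids, rootDistance = unname(D), segment = segment, ns = ns,
        stringsAsFactors = FALSE, row.names = NULL
    )

    # deepest containing node per locus (containing nodes form a chain)
    deepest <- rep(NA_character_, tree@nBins)
    deepestD <- rep(-1L, tree@nBins)
    for (id in ids) {
        loci <- nodes[[id]]$loci
        upd <- D[[id]] > deepestD[loci]
        deepest[loci[upd]] <- id
        deepestD[loci[upd]] <- D[[id]]
    }
    idx <- match(deepest, ids)
    locusNs <- ns[idx]
    aboveTop <- segment[idx] == "above_top"
    locusNs[aboveTop & is.na(locusNs)] <- 0
    perLocus <- data.frame(
        locus = seq_len(tree@nBins), nodeId = deepest, ns = locusNs,
        stringsAsFactors = FALSE
    )
    list(perNode = perNode, perLocus = perLocus)
}

#' Write per-locus nestedness as a BED-like table
#'
#' Columns: chrom, bin start (0-based), bin end, deepest node id, NS.
#'
#' @param ns result of [nestedness()].
#' @param bins the bin table ([GenomicRanges::GRanges] with `binId`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
nestednessToBed <- function(ns, bins, path) {
    pl <- ns$perLocus
    b <- bins[match(pl$locus, bins$binId)]
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(b)),
        start = GenomicRanges::start(b) - 1L,
        end = GenomicRanges::end(b),
        name = pl$nodeId,
        score = pl$ns
    )
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}
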