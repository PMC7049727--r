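#' Variation of information between two clusterings
#'
#' `VI(C, C') = H(C) + H(C') - 2 I(C, C')`, with entropy and mutual
#' information computed from the empirical cluster and joint frequencies in
#' natural logarithm (nats), and `0 log 0 = 0`. VI is a metric on
#' partitions: symmetric, non-negative, zero iff the partitions are equal,
#' and bounded by `log(N)`.
#'
#' @param c1,c2 [FlatClustering] objects (or plain label vectors) over the
#'   same loci universe.
#' @return a list of class `"viResult"` with `vi`, `h1`, `h2` and `mi`
#'   (all in nats).
#' @examples
#' variationOfInformation(c(1, 1, 2, 2), c(1, 2, 1, 2))$vi # 2 * log(2)
#' @export
variationOfInformation <- function(c1, c2) {
    a1 <- if (is(c1, "FlatClustering")) c1@assignment else as.character(c1)
    a2 <- if (is(c2, "FlatClustering")) c2@assignment else as.character(c2)
    if (length(a1) != length(a2)) {
        stop(sprintf(
            "clusterings are over different universes (%d vs %d loci)",
            length(a1), length(a2)
        ))
    }
    n <- length(a1)
    joint <- table(a1, a2) / n
    p1 <- rowSums(joint)
    p2 <- colSums(joint)
    ent <- function(p) {
        p <- p[p > 0]
        -sum(p * log(p))
    }
    h1 <- ent(p1)
    h2 <- ent(p2)
    nz <- joint > 0
    mi <- sum(joint[nz] * log(joint[nz] / outer(p1, p2)[nz]))
    structure(
        list(vi = h1 + h2 - 2 * mi, h1 = h1, h2 = h2, mi = mi),
        class = "viResult"
    )
}

#' @export
print.viResult <- function(x, ...) {
    cat(sprintf(
        "VI = %.4f nats (H = %.4f, H' = %.4f, I = %.4f)\n",
        x$vi, x$h1, x$h2, x$mi
    ))
    invisible(x)
}

#' Flat clustering induced by the enclaves of a tree
#'
#' Each chosen enclave (bottom by default, or top) becomes one cluster made
#' of its loci; loci covered by no chosen enclave are pooled into a single
#' catch-all cluster so the number of clusters stays comparable to
#' reference clusterings. Enclaves at a fixed level are pairwise disjoint
#' by construction of the tree.
#'
#' @param tree an [EnclaveTree].
#' @param labels its [EnclaveLabels] (computed if missing).
#' @param level `"bottom"` or `"top"`.
#' @param unassignedLabel label of the catch-all cluster.
#' @return a [FlatClustering] over the tree's loci universe.
#' @export
enclaveClustering <- function(tree, labels = labelEnclaves(tree),
                              level = c("bottom", "top"),
                              unassignedLabel = "unclustered") {
    level <- match.arg(level)
    chosen <- if (level == "bottom") labels@bottom else labels@top
    assignment <- rep(unassignedLabel, tree@nBins)
    for (id in chosen) {
        loci <- tree@nodes[[id]]$loci
        if (any(assignment[loci] != unassignedLabel)) {
            stop("internal consistency error: chosen enclaves overlap")
        }
        assignment[loci] <- id
    }
    FlatClustering(assignment)
}

#' Tree-matched random clustering
#'
#' Draws a random partition tree with the same topology and per-node loci
#' counts as the template (the null model of the variation-of-information
#' significance test): at each bisection the child memberships are drawn
#' uniformly without replacement from the parent's loci. The induced flat
#' clustering is extracted exactly as for the real tree (same landmark
#' node ids, same catch-all rule).
#'
#' @param tree template [EnclaveTree].
#' @param seed integer seed; identical seeds give identical draws.
#' @param labels the template's [EnclaveLabels] (computed if missing);
#'   topology is shared, so the labels carry over to the random tree.
#' @param level enclave level for the induced clustering.
#' @return list with `tree` (the random [EnclaveTree]) and `clustering`
#'   (its induced [FlatClustering]).
#' @export
randomTreeClustering <- function(tree, seed, labels = labelEnclaves(tree),
                                 level = "bottom") {
    nodes <- tree@nodes
    D <- vapply(nodes, function(nd) nd$rootDistance, integer(1))
    depthOrder <- names(nodes)[order(D)]
    rnd <- nodes
    withr::with_seed(as.integer(seed), {
        for (id in depthOrder) {
            nd <- nodes[[id]]
            myLoci <- rnd[[id]]$loci
            if (!length(nd$children)) next
            if (nd$branchKind == "split") {
                n0 <- length(nodes[[nd$children[1]]]$loci)
                pick <- sample(myLoci, n0)
                rnd[[nd$children[1]]]$loci <- sort(pick)
                rnd[[nd$children[2]]]$loci <- sort(setdiff(myLoci, pick))
            } else {
                n0 <- length(nodes[[nd$children[1]]]$loci)
                pick <- sample(myLoci, n0)
                rnd[[nd$children[1]]]$loci <- sort(pick)
                rnd[[id]]$auxiliary <- sort(setdiff(myLoci, pick))
            }
        }
    })
    rt <- new("EnclaveTree",
        nodes = rnd, rootId = tree@rootId, chrom = tree@chrom,
        resolution = tree@resolution, nBins = tree@nBins
    )
    list(
        tree = rt,
        clustering = enclaveClustering(rt, labels, level = level)
    )
}

#' Empirical P-value from a null sample of VI values
#'
#' `p = (r + 1) / (n + 1)`, where `r` is the number of null draws with a VI
#' strictly smaller than the observed one (ties count as not smaller) and
#' `n` is the total number of clusterings considered, i.e. the number of
#' random draws plus one (the observed clustering): 500 draws give
#' `n = 501` and a minimum attainable `p` of `1/502`.
#'
#' @param observedVi observed VI against the reference clustering.
#' @param nullVis numeric vector of VI values of the random clusterings
#'   against the same reference.
#' @return list with `r`, `n` and `p`.
#' @export
empiricalPValue <- function(observedVi, nullVis) {
    if (!length(nullVis)) stop("empty null sample")
    r <- sum(nullVis < observedVi)
    n <- length(nullVis) + 1L
    list(r = r, n = n, p = (r + 1) / (n + 1))
}

#' VI significance of an enclave clustering against a reference
#'
#' Convenience wrapper running the full validation of one chromosome:
#' observed VI between the enclave clustering and the reference, `draws`
#' tree-matched random clusterings, their null VI distribution and the
#' empirical P-value.
#'
#' @param tree an [EnclaveTree].
#' @param reference a [FlatClustering] on the same loci universe (e.g. TADs
#'   or compartments mapped to the bin grid).
#' @param draws number of random clusterings (paper default 500).
#' @param seed master seed; draw `k` uses `seed + k`.
#' @param labels,level passed to [enclaveClustering()].
#' @return list with `observedVi`, `nullVis`, `r`, `n`, `p`.
#' @export
viSignificance <- function(tree, reference, draws = 500L, seed = 1234L,
                           labels = labelEnclaves(tree), level = "bottom") {
    obs <- variationOfInformation(
        enclaveClustering(tree, labels, level = level), reference
    )$vi
    nullVis <- vapply(seq_len(draws), function(k) {
        rc <- randomTreeClustering(tree, seed = as.integer(seed) + k,
            labels = labels, level = level)
        variationOfInformation(rc$clustering, reference)$vi
    }, numeric(1))
    ep <- empiricalPValue(obs, nullVis)
    c(list(observedVi = obs, nullVis = nullVis), ep)
}
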