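# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (double loops, exhaustive enumeration) and shares no
# code with the package implementation it checks.

# random symmetric non-negative weight matrix with strictly positive entries
randomWeightMatrix <- function(n, seed, positive = TRUE) {
    withr::with_seed(seed, {
        w <- matrix(stats::runif(n * n, min = if (positive) 0.05 else 0), n, n)
        w <- (w + t(w)) / 2
        w
    })
}

# expansion metric by literal double loop over ordered pairs
bruteExpansion <- function(w, c1, c2) {
    num <- 0
    den <- 0
    for (x in c1) {
        for (y in c2) num <- num + w[x, y]
        for (y in c1) den <- den + w[x, y]
    }
    num / den
}

# VI from an explicitly accumulated contingency table
bruteVI <- function(a, b) {
    a <- as.character(a)
    b <- as.character(b)
    n <- length(a)
    ka <- unique(a)
    kb <- unique(b)
    pa <- vapply(ka, function(k) sum(a == k) / n, numeric(1))
    pb <- vapply(kb, function(k) sum(b == k) / n, numeric(1))
    h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
    mi <- 0
    for (i in seq_along(ka)) {
        for (j in seq_along(kb)) {
            pij <- sum(a == ka[i] & b == kb[j]) / n
            if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
        }
    }
    unname(h(pa) + h(pb) - 2 * mi)
}

# pairwise interval intersection in bp, O(n * m)
bruteOverlapBp <- function(siteStart, siteEnd, clStart, clEnd) {
    # 1-based closed coordinates, like GRanges
    total <- numeric(length(siteStart))
    for (i in seq_along(siteStart)) {
        for (j in seq_along(clStart)) {
            ov <- min(siteEnd[i], clEnd[j]) - max(siteStart[i], clStart[j]) + 1
            if (ov > 0) total[i] <- total[i] + ov
        }
    }
    total
}

# exhaustive normalized-cut enumeration over all bipartitions (n <= 12);
# returns ncut values sorted ascending with their bipartitions
enumNormCut <- function(w) {
    n <- nrow(w)
    deg <- rowSums(w)
    res <- list()
    for (mask in seq_len(2^(n - 1) - 1)) {
        side <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
        a <- which(side)
        b <- which(!side)
        cut <- sum(w[a, b])
        nc <- cut / sum(deg[a]) + cut / sum(deg[b])
        res[[length(res) + 1]] <- list(a = a, b = b, ncut = nc)
    }
    res[order(vapply(res, function(r) r$ncut, numeric(1)))]
}

# two-sided exact Poisson p-value by direct tail summation over the density
brutePoissonTwoSided <- function(x, lambda) {
    kmax <- max(x, ceiling(lambda + 20 * sqrt(lambda) + 50))
    d <- stats::dpois(0:kmax, lambda)
    sum(d[d <= stats::dpois(x, lambda) * (1 + 1e-07)])
}

# naive enclave labelling: per node, independently walk up to the root and
# recursively scan the whole subtree (no shared precomputation)
naiveLabelScan <- function(tree) {
    nodes <- tree@nodes
    kindOf <- function(id) nodes[[id]]$branchKind
    ancestorsAllSplit <- function(id) {
        p <- nodes[[id]]$parent
        while (!is.na(p)) {
            if (kindOf(p) != "split") return(FALSE)
            p <- nodes[[p]]$parent
        }
        TRUE
    }
    subtreeStripOnly <- function(id) {
        if (kindOf(id) == "split") return(FALSE)
        all(vapply(nodes[[id]]$children, subtreeStripOnly, logical(1)))
    }
    ids <- names(nodes)
    bottom <- ids[vapply(ids, function(id) {
        p <- nodes[[id]]$parent
        !is.na(p) && kindOf(p) == "split" && subtreeStripOnly(id)
    }, logical(1))]
    top <- setdiff(ids[vapply(ids, function(id) {
        kindOf(id) == "strip" && ancestorsAllSplit(id)
    }, logical(1))], bottom)
    leaves <- setdiff(
        ids[vapply(ids, function(id) length(nodes[[id]]$children) == 0L,
            logical(1))],
        c(top, bottom)
    )
    list(top = sort(top), bottom = sort(bottom), leaves = sort(leaves))
}

# random EnclaveTree fixture: recursive random bisections with random branch
# kinds, valid loci nesting, built directly (not via the clustering code)
randomTreeFixture <- function(nLoci, seed, pSplit = 0.5, pStrip = 0.35) {
    withr::with_seed(seed, {
        nodes <- list()
        addNode <- function(id, parent, loci, depth) {
            nodes[[id]] <<- list(
                id = id, parent = parent, children = character(),
                loci = sort(loci), auxiliary = integer(),
                expansion = if (is.na(parent)) NA_real_ else stats::runif(1, 0, 0.99),
                branchKind = "none", rootDistance = depth,
                fiedlerValue = NA_real_, termination = NA_character_
            )
            if (length(loci) <= 2L) return(invisible())
            u <- stats::runif(1)
            if (u < pSplit) {
                nodes[[id]]$branchKind <<- "split"
                k <- sample(seq_len(length(loci) - 1L), 1)
                a <- sample(loci, k)
                ids <- paste0(id, c(".0", ".1"))
                nodes[[id]]$children <<- ids
                addNode(ids[1], id, a, depth + 1L)
                addNode(ids[2], id, setdiff(loci, a), depth + 1L)
            } else if (u < pSplit + pStrip) {
                nodes[[id]]$branchKind <<- "strip"
                k <- sample(seq_len(length(loci) - 1L), 1)
                a <- sample(loci, k)
                cid <- paste0(id, ".0")
                nodes[[id]]$children <<- cid
                nodes[[id]]$auxiliary <<- sort(setdiff(loci, a))
                addNode(cid, id, a, depth + 1L)
            } else {
                nodes[[id]]$termination <<- "stop"
            }
        }
        addNode("R", NA_character_, seq_len(nLoci), 0L)
        new("EnclaveTree",
            nodes = nodes, rootId = "R", chrom = "chrT",
            resolution = 1000L, nBins = as.integer(nLoci)
        )
    })
}

# random flat clustering over n loci with <= k clusters
randomClustering <- function(n, k, seed) {
    withr::with_seed(seed, FlatClustering(sample(seq_len(k), n, replace = TRUE)))
}

# memoized shared fixture: one simulated map taken through the full pipeline
.fixtureCache <- new.env(parent = emptyenv())
sharedPipelineFixture <- function() {
    if (is.null(.fixtureCache$pipeline)) {
        sim <- simulateContactMap(seed = 42L)
        map <- boxcoxScale(krBalance(sim$map))
        tree <- suppressMessages(buildEnclaveTree(map))
        labels <- labelEnclaves(tree)
        .fixtureCache$pipeline <- list(
            sim = sim, map = map, tree = tree, labels = labels,
            ns = nestedness(tree, labels)
        )
    }
    .fixtureCache$pipeline
}

# wrap a plain symmetric matrix in a ContactMap for stage-function tests
makeTestMap <- function(w, stage = "raw", resolution = 1000L,
                        chrom = "chrT") {
    n <- nrow(w)
    bins <- GenomicRanges::GRanges(
        chrom,
        IRanges::IRanges(
            start = (seq_len(n) - 1L) * resolution + 1L,
            width = resolution
        )
    )
    bins$binId <- seq_len(n)
    new("ContactMap",
        matrix = w, bins = bins, resolution = as.integer(resolution),
        chrom = chrom, stage = stage,
        dropped = GenomicRanges::GRanges(), meta = list()
    )
}

# tiny GRanges helpers for interval fixtures
grIv <- function(starts, ends, chrom = "chrS") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts, end = ends))
}
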