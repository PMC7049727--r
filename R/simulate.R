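#' Describe a planted interaction-block hierarchy
#'
#' A planted hierarchy is a tree of loci sets: each node is a planted
#' cluster with a mean within-cluster interaction weight added on top of
#' its ancestors' weights and the distance-decay background; children are
#' nested inside their parents and siblings are disjoint. Blocks may be
#' genomically non-contiguous, which is how the plaid-pattern (enclave)
#' structure of real contact maps is emulated.
#'
#' @param blocks list of top-level block specs, each created with
#'   [plantedBlock()].
#' @return an object of class `"plantedHierarchy"`.
#' @export
plantedHierarchy <- function(blocks) {
    h <- structure(list(blocks = blocks), class = "plantedHierarchy")
    validateBlocks <- function(nodes, parentLoci = NULL) {
        seen <- integer()
        for (nd in nodes) {
            stopifnot(is.list(nd), !is.null(nd$loci), !is.null(nd$weight))
            if (nd$weight <= 0) stop("block weights must be positive")
            if (anyDuplicated(nd$loci)) {
                stop("block '", nd$name, "' has duplicated loci")
            }
            if (!is.null(parentLoci) && !all(nd$loci %in% parentLoci)) {
                stop("block '", nd$name,
                    "' is not nested inside its parent")
            }
            if (length(intersect(seen, nd$loci))) {
                stop("sibling blocks overlap at block '", nd$name, "'")
            }
            seen <- c(seen, nd$loci)
            if (length(nd$children)) validateBlocks(nd$children, nd$loci)
        }
    }
    validateBlocks(blocks)
    h
}

#' @rdname plantedHierarchy
#' @param name block label (used in the ground-truth clustering).
#' @param loci integer bin indices of the block (1-based, possibly
#'   non-contiguous).
#' @param weight mean within-block interaction weight added by this node.
#' @param children list of nested child blocks.
#' @param shell mark this block as a loose shell: a loci set that interacts
#'   with its parent cluster above background but is not compact enough to
#'   be a cluster of its own (it emulates the shell of long-ranging DNA
#'   loops around a tightly packed core, the structure shed by strip
#'   bisections). Shell blocks are excluded from the ground-truth
#'   clustering of [plantedClustering()].
#' @export
plantedBlock <- function(name, loci, weight, children = list(),
                         shell = FALSE) {
    list(
        name = name, loci = sort(as.integer(loci)),
        weight = weight, children = children, shell = shell
    )
}

#' @export
print.plantedHierarchy <- function(x, ...) {
    walk <- function(nodes, indent) {
        for (nd in nodes) {
            cat(sprintf(
                "%s%s: %d loci, weight %g\n",
                strrep("  ", indent), nd$name, length(nd$loci), nd$weight
            ))
            walk(nd$children, indent + 1)
        }
    }
    cat("plantedHierarchy\n")
    walk(x$blocks, 1)
    invisible(x)
}

#' Default planted hierarchy: core blocks wrapped in loose shells
#'
#' Three superblocks of equal size. Each consists of a compact core of two
#' leaf blocks plus a small loose shell: shell loci are attached to the
#' whole superblock just above background and cohere weakly among
#' themselves, emulating the shell of long-ranging contacts around tightly
#' packed cores. On such a map the recursion first splits off the
#' superblocks, strips each shell (creating the top enclaves), then splits
#' the cores into the leaf blocks (the bottom enclaves), and strips inside
#' the blocks down to the leaves — populating every segment of the
#' nestedness scale.
#'
#' One superblock interleaves its two blocks in alternating runs (the
#' plaid pattern) and one contains a block whose loci form two distant
#' genomic intervals — the defining non-contiguous enclave case. Requires
#' `nBins` divisible by 18.
#'
#' @param nBins number of bins (default 144).
#' @param superWeight attachment weight of the superblock (all pairs,
#'   shell included).
#' @param coreWeight additional weight among core loci.
#' @param blockWeight additional weight within each leaf block.
#' @param shellWeight additional weight among shell loci.
#' @return a [plantedHierarchy()].
#' @export
examplePlantedHierarchy <- function(nBins = 144L, superWeight = 5,
                                    coreWeight = 45, blockWeight = 50,
                                    shellWeight = 20) {
    nBins <- as.integer(nBins)
    stopifnot(nBins %% 18L == 0L)
    s <- nBins %/% 3L # superblock size
    nShell <- s %/% 6L # shell loci per superblock
    super <- function(tag, loci, splitBlocks) {
        # every 6th bin is shell, the rest is core
        shellIdx <- loci[seq_along(loci) %% 6L == 0L][seq_len(nShell)]
        core <- setdiff(loci, shellIdx)
        blocks <- splitBlocks(core)
        plantedBlock(tag, loci, superWeight, list(
            plantedBlock(paste0(tag, "core"), core, coreWeight, list(
                plantedBlock(paste0(tag, "a"), blocks[[1]], blockWeight),
                plantedBlock(paste0(tag, "b"), blocks[[2]], blockWeight)
            )),
            plantedBlock(paste0(tag, "shell"), shellIdx, shellWeight,
                shell = TRUE)
        ))
    }
    half <- function(core) {
        b <- length(core) %/% 2L
        list(core[seq_len(b)], core[(b + 1L):length(core)])
    }
    interleaved <- function(core) {
        # alternating runs: the plaid pattern
        run <- max(1L, length(core) %/% 6L)
        phase <- ((seq_along(core) - 1L) %/% run) %% 2L
        list(core[phase == 0L], core[phase == 1L])
    }
    distantEnds <- function(core) {
        # one block from the two distant ends, one from the middle
        q <- length(core) %/% 4L
        ends <- c(
            core[seq_len(q)],
            core[(length(core) - q + 1L):length(core)]
        )
        list(ends, setdiff(core, ends))
    }
    plantedHierarchy(list(
        super("S1", seq_len(s), half),
        super("S2", s + seq_len(s), interleaved),
        super("S3", 2L * s + seq_len(s), distantEnds)
    ))
}

#' Ground-truth flat clustering of a planted hierarchy
#'
#' Non-shell leaf blocks become clusters; shell loci and loci in no leaf
#' block are labelled `"background"`.
#'
#' @param hierarchy a [plantedHierarchy()].
#' @param nBins loci universe size.
#' @return a [FlatClustering].
#' @export
plantedClustering <- function(hierarchy, nBins) {
    assignment <- rep("background", nBins)
    walk <- function(nodes) {
        for (nd in nodes) {
            if (length(nd$children)) {
                walk(nd$children)
            } else if (!isTRUE(nd$shell)) {
                assignment[nd$loci] <<- nd$name
            }
        }
    }
    walk(hierarchy$blocks)
    FlatClustering(assignment)
}

#' Expected contact matrix of a planted hierarchy
#'
#' `E[i, j] = background * |i - j|^(-alpha)` for `i != j`, plus the summed
#' weights of all planted nodes containing both `i` and `j`. The diagonal
#' is 0: self-contact counts are dominated by ligation artifacts and carry
#' no clustering information, and the decay form is undefined at distance
#' zero.
#'
#' @param hierarchy a [plantedHierarchy()].
#' @param nBins number of bins.
#' @param background decay amplitude at distance 1 (bins).
#' @param alpha decay exponent (default 1, a fractal-globule-like decay).
#' @return symmetric `nBins x nBins` matrix of expected weights.
#' @export
expectedContactMatrix <- function(hierarchy, nBins, background = 10,
                                  alpha = 1) {
    d <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
    e <- matrix(0, nBins, nBins)
    off <- d > 0
    e[off] <- background * d[off]^(-alpha)
    walk <- function(nodes) {
        for (nd in nodes) {
            e[nd$loci, nd$loci] <<- e[nd$loci, nd$loci] + nd$weight
            walk(nd$children)
        }
    }
    walk(hierarchy$blocks)
    diag(e) <- 0
    e
}

#' Simulate a contact map with planted nested blocks
#'
#' Draws a symmetric count matrix whose expectation is
#' [expectedContactMatrix()], with Poisson noise (optionally
#' negative-binomial for over-dispersion, or no noise at all), and wraps it
#' in a [ContactMap] together with the ground truth. Identical seeds and
#' specs give bit-identical matrices.
#'
#' @param hierarchy a [plantedHierarchy()]; default [examplePlantedHierarchy()].
#' @param nBins number of bins (at least the total planted loci).
#' @param resolution bin width in bp.
#' @param background,alpha distance-decay background, see
#'   [expectedContactMatrix()].
#' @param noise `"poisson"`, `"nbinom"` or `"none"`.
#' @param dispersion over-dispersion of the negative binomial
#'   (`variance = mu + dispersion * mu^2`).
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return list with `map` (a raw-stage [ContactMap]), `truth` (the
#'   hierarchy) and `clustering` (the ground-truth [FlatClustering] of
#'   leaf blocks).
#' @export
simulateContactMap <- function(hierarchy = examplePlantedHierarchy(nBins),
                               nBins = 144L, resolution = 50000L,
                               background = 10, alpha = 1,
                               noise = c("poisson", "nbinom", "none"),
                               dispersion = 0.1, chrom = "chrS",
                               seed = 1L) {
    noise <- match.arg(noise)
    nBins <- as.integer(nBins)
    maxLocus <- max(c(0L, unlist(lapply(hierarchy$blocks,
        function(nd) nd$loci))))
    if (maxLocus > nBins) {
        stop("hierarchy loci exceed nBins")
    }
    e <- expectedContactMatrix(hierarchy, nBins, background, alpha)
    w <- e
    if (noise != "none") {
        ut <- which(upper.tri(e))
        draws <- withr::with_seed(as.integer(seed), {
            if (noise == "poisson") {
                stats::rpois(length(ut), e[ut])
            } else {
                stats::rnbinom(length(ut), mu = e[ut], size = 1 / dispersion)
            }
        })
        w <- matrix(0, nBins, nBins)
        w[ut] <- draws
        w <- w + t(w)
    }
    if (any(rowSums(w) == 0)) {
        stop("simulated matrix has all-zero rows; ",
            "increase background or coverage of the planted blocks")
    }
    bins <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(
            start = (seq_len(nBins) - 1L) * as.integer(resolution) + 1L,
            width = as.integer(resolution)
        )
    )
    bins$binId <- seq_len(nBins)
    map <- new("ContactMap",
        matrix = w, bins = bins, resolution = as.integer(resolution),
        chrom = chrom, stage = "raw",
        dropped = GenomicRanges::GRanges(), meta = list()
    )
    list(
        map = map,
        truth = hierarchy,
        clustering = plantedClustering(hierarchy, nBins)
    )
}

#' Simulate a feature track with planted per-locus enrichment
#'
#' Sites are placed with a Poisson rate of `baseRate` sites per bin,
#' multiplied by `enrichment` on the target loci; site starts are uniform
#' within their bin, lengths and intensities log-normal. Deterministic
#' given the seed.
#'
#' @param bins bin table ([GenomicRanges::GRanges] with `binId`).
#' @param targetLoci integer bin indices carrying the enrichment.
#' @param enrichment rate multiplier on target loci (1 = uniform track).
#' @param baseRate baseline expected sites per bin.
#' @param targetRate expected sites per target bin; defaults to
#'   `baseRate * enrichment` (set explicitly for a zero baseline).
#' @param meanLength mean site length in bp.
#' @param seed integer seed.
#' @return a GRanges with a `signalValue` intensity column.
#' @export
simulateFeatureTrack <- function(bins, targetLoci = integer(),
                                 enrichment = 1, baseRate = 1,
                                 targetRate = NULL,
                                 meanLength = NULL, seed = 1L) {
    n <- length(bins)
    res <- GenomicRanges::width(bins)[1]
    if (is.null(meanLength)) meanLength <- max(10, res %/% 25)
    if (is.null(targetRate)) targetRate <- baseRate * enrichment
    rate <- rep(baseRate, n)
    rate[targetLoci] <- targetRate
    chromEnd <- max(GenomicRanges::end(bins))
    withr::with_seed(as.integer(seed), {
        counts <- stats::rpois(n, rate)
        binIdx <- rep(seq_len(n), counts)
        total <- sum(counts)
        offs <- floor(stats::runif(total) * res)
        starts <- GenomicRanges::start(bins)[binIdx] + offs
        lens <- pmax(10, round(stats::rlnorm(
            total,
            meanlog = log(meanLength), sdlog = 0.5
        )))
        ends <- pmin(starts + lens - 1, chromEnd)
        gr <- GenomicRanges::GRanges(
            seqnames = rep(
                as.character(GenomicRanges::seqnames(bins))[1], total
            ),
            ranges = IRanges::IRanges(start = starts, end = ends)
        )
        gr$signalValue <- stats::rlnorm(total, meanlog = 1, sdlog = 0.5)
        sort(gr)
    })
}

#' Simulate DNA loops within and between clusters
#'
#' Generates loop anchor pairs on the bin grid: `nWithin` loops with both
#' anchors in bins of the same cluster and `nBetween` loops bridging two
#' different clusters. Used to exercise loop-integration statistics.
#'
#' @param clustering a [FlatClustering].
#' @param bins aligned bin table.
#' @param nWithin,nBetween numbers of within- and between-cluster loops.
#' @param anchorBp anchor width in bp.
#' @param unassignedLabel catch-all label excluded from cluster choice.
#' @param seed integer seed.
#' @return a [S4Vectors::Pairs] of anchor GRanges.
#' @export
simulateLoops <- function(clustering, bins, nWithin = 20L, nBetween = 10L,
                          anchorBp = NULL, unassignedLabel = "unclustered",
                          seed = 1L) {
    lab <- clustering@assignment[bins$binId]
    res <- GenomicRanges::width(bins)[1]
    if (is.null(anchorBp)) anchorBp <- max(10L, res %/% 5L)
    ok <- names(which(table(lab[lab != unassignedLabel]) >= 2))
    if (length(ok) < 1L) stop("need at least one cluster with 2+ loci")
    anchorAt <- function(locus) {
        s <- GenomicRanges::start(bins)[locus]
        GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(bins))[1],
            IRanges::IRanges(start = s, width = anchorBp)
        )
    }
    withr::with_seed(as.integer(seed), {
        a1 <- GenomicRanges::GRanges()
        a2 <- GenomicRanges::GRanges()
        for (k in seq_len(nWithin)) {
            cl <- sample(ok, 1)
            pair <- sample(which(lab == cl), 2)
            a1 <- c(a1, anchorAt(pair[1]))
            a2 <- c(a2, anchorAt(pair[2]))
        }
        if (nBetween > 0L && length(ok) >= 2L) {
            for (k in seq_len(nBetween)) {
                cls <- sample(ok, 2)
                a1 <- c(a1, anchorAt(sample(which(lab == cls[1]), 1)))
                a2 <- c(a2, anchorAt(sample(which(lab == cls[2]), 1)))
            }
        }
        S4Vectors::Pairs(a1, a2)
    })
}
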