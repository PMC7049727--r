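#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors Pairs
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom stats kmeans quantile IQR p.adjust poisson.test
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' ContactMap: a per-chromosome Hi-C contact matrix over genomic bins
#'
#' A `ContactMap` holds the symmetric, non-negative interaction matrix of one
#' chromosome together with the ordered table of retained genomic bins, the
#' bin resolution, and the processing stage (`"raw"`, `"kr_normalized"` or
#' `"boxcox_scaled"`). Bins dropped as unmappable (zero total contact weight)
#' are recorded in the `dropped` slot. Entry `(i, j)` of the matrix is the
#' interaction weight between the i-th and j-th retained bins.
#'
#' @slot matrix symmetric non-negative numeric matrix, one row/column per
#'   retained bin.
#' @slot bins [GenomicRanges::GRanges] of the retained bins, sorted by start,
#'   with an integer metadata column `binId` equal to the matrix row index.
#' @slot resolution integer, bin width in bp.
#' @slot chrom chromosome name.
#' @slot stage processing stage.
#' @slot dropped GRanges of bins removed as unmappable (may be empty).
#' @slot meta list of stage-specific fit details (KR scaling vector,
#'   Box-Cox fit, applied shift).
#'
#' @seealso [readContactTriples()], [krBalance()], [boxcoxScale()]
#' @export
setClass("ContactMap",
    slots = c(
        matrix = "matrix",
        bins = "GRanges",
        resolution = "integer",
        chrom = "character",
        stage = "character",
        dropped = "GRangesOrNULL",
        meta = "list"
    ),
    prototype = prototype(dropped = NULL, meta = list())
)

setValidity("ContactMap", function(object) {
    w <- object@matrix
    msg <- character()
    if (nrow(w) != ncol(w)) {
        msg <- c(msg, "contact matrix must be square")
    }
    if (nrow(w) < 2L) {
        msg <- c(msg, "a contact map needs at least 2 retained bins")
    }
    if (nrow(w) != length(object@bins)) {
        msg <- c(msg, "number of bins must match matrix dimension")
    }
    if (any(w < 0)) {
        msg <- c(msg, "contact weights must be non-negative")
    }
    if (max(abs(w - t(w))) > 1e-8 * max(1, max(abs(w)))) {
        msg <- c(msg, "contact matrix must be symmetric")
    }
    if (any(rowSums(w) == 0)) {
        msg <- c(msg, "retained bins must not have all-zero rows")
    }
    if (!object@stage %in% c("raw", "kr_normalized", "boxcox_scaled")) {
        msg <- c(msg, "stage must be raw, kr_normalized or boxcox_scaled")
    }
    if (is.null(object@bins$binId) ||
        !identical(as.integer(object@bins$binId), seq_len(nrow(w)))) {
        msg <- c(msg, "bins$binId must be the contiguous sequence 1..N")
    }
    if (length(msg)) msg else TRUE
})

#' EnclaveTree: the partition tree produced by recursive spectral bisection
#'
#' Nodes are stored as a named list of records. Every node carries the loci
#' (bin indices) of its cluster, its parent and children ids, its own
#' expansion value (the insulation score it obtained when its parent was
#' bisected; `NA` for the root), the branch kind of its own bisection
#' (`"split"`, `"strip"` or `"none"`), its root distance (number of branches
#' from the root), the auxiliary loci shed by a strip bisection, and a
#' termination reason for childless nodes.
#'
#' Node ids are deterministic path strings: the root is `"R"`, children are
#' `"<parent>.0"` / `"<parent>.1"`, so identical inputs and seeds give
#' byte-identical serialized trees.
#'
#' @slot nodes named list of node records.
#' @slot rootId id of the root node.
#' @slot chrom,resolution provenance of the contact map the tree was built on.
#' @slot nBins number of loci in the root (the whole chromosome).
#'
#' @seealso [buildEnclaveTree()], [labelEnclaves()], [nestedness()]
#' @export
setClass("EnclaveTree",
    slots = c(
        nodes = "list",
        rootId = "character",
        chrom = "character",
        resolution = "integer",
        nBins = "integer"
    )
)

setValidity("EnclaveTree", function(object) {
    nodes <- object@nodes
    msg <- character()
    if (!object@rootId %in% names(nodes)) {
        msg <- c(msg, "rootId must name a node")
    }
    for (nd in nodes) {
        for (ch in nd$children) {
            if (!ch %in% names(nodes)) {
                msg <- c(msg, sprintf("child '%s' of '%s' missing", ch, nd$id))
                next
            }
            if (!all(nodes[[ch]]$loci %in% nd$loci)) {
                msg <- c(msg, sprintf(
                    "loci of child '%s' are not a subset of '%s'", ch, nd$id
                ))
            }
        }
        if (!is.na(nd$parent) && !nd$parent %in% names(nodes)) {
            msg <- c(msg, sprintf("parent of '%s' missing", nd$id))
        }
    }
    root <- nodes[[object@rootId]]
    if (!is.null(root) && length(root$loci) != object@nBins) {
        msg <- c(msg, "root must contain all retained bins")
    }
    if (length(msg)) msg else TRUE
})

#' FlatClustering: a disjoint assignment of loci to clusters
#'
#' A plain per-locus label vector over a universe of N loci, used for
#' variation-of-information comparisons. Labels are opaque strings; the
#' number of clusters K is the number of distinct labels.
#'
#' @slot assignment character vector of length N; element i is the cluster
#'   label of locus i.
#'
#' @seealso [variationOfInformation()], [enclaveClustering()]
#' @export
setClass("FlatClustering", slots = c(assignment = "character"))

setValidity("FlatClustering", function(object) {
    if (length(object@assignment) < 1L) {
        return("assignment must be non-empty")
    }
    if (anyNA(object@assignment)) {
        return("every locus must have exactly one label (no NA)")
    }
    TRUE
})

#' EnclaveLabels: the landmark nodes of an EnclaveTree
#'
#' Holds the ids of top enclaves (first strip branchings reached through
#' splits only), bottom enclaves (last split children with only strip
#' branchings at or below them) and leaves (the remaining childless nodes).
#' The three sets are pairwise disjoint.
#'
#' @slot top,bottom,leaves character vectors of node ids.
#' @seealso [labelEnclaves()]
#' @export
setClass("EnclaveLabels",
    slots = c(top = "character", bottom = "character", leaves = "character")
)

setValidity("EnclaveLabels", function(object) {
    sets <- list(object@top, object@bottom, object@leaves)
    if (anyDuplicated(unlist(sets))) {
        return("top, bottom and leaf sets must be pairwise disjoint")
    }
    TRUE
})

#' @describeIn FlatClustering constructor from a label vector
#' @param labels vector of per-locus cluster labels (coerced to character).
#' @export
FlatClustering <- function(labels) {
    new("FlatClustering", assignment = as.character(labels))
}
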