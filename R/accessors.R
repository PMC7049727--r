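#' @rdname ContactMap-class
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@matrix)

#' @rdname ContactMap-class
#' @export
setMethod("contactBins", "ContactMap", function(x) x@bins)

#' @rdname ContactMap-class
#' @export
setMethod("mapResolution", "ContactMap", function(x) x@resolution)

#' @rdname ContactMap-class
#' @export
setMethod("chromName", "ContactMap", function(x) x@chrom)

#' @rdname ContactMap-class
#' @export
setMethod("mapStage", "ContactMap", function(x) x@stage)

#' @rdname ContactMap-class
#' @export
setMethod("droppedBins", "ContactMap", function(x) x@dropped)

#' @rdname ContactMap-class
#' @export
setMethod("boxcoxFit", "ContactMap", function(x) x@meta$boxcox)

setMethod("show", "ContactMap", function(object) {
    cat(sprintf(
        "ContactMap: %s, %d bins at %d bp (%s)\n",
        object@chrom, nrow(object@matrix), object@resolution, object@stage
    ))
    if (!is.null(object@dropped) && length(object@dropped)) {
        cat(sprintf("  %d unmappable bin(s) dropped\n", length(object@dropped)))
    }
})

#' @rdname EnclaveTree-class
#' @export
setMethod("nodeIds", "EnclaveTree", function(x) names(x@nodes))

#' @rdname EnclaveTree-class
#' @export
setMethod("getNode", "EnclaveTree", function(x, id) {
    nd <- x@nodes[[id]]
    if (is.null(nd)) stop("no node with id '", id, "'")
    nd
})

#' @rdname EnclaveTree-class
#' @export
setMethod("rootId", "EnclaveTree", function(x) x@rootId)

#' @rdname EnclaveTree-class
#' @export
setMethod("length", "EnclaveTree", function(x) length(x@nodes))

setMethod("show", "EnclaveTree", function(object) {
    kinds <- vapply(object@nodes, function(nd) nd$branchKind, character(1))
    cat(sprintf(
        "EnclaveTree: %s, %d loci, %d nodes (%d split, %d strip), depth %d\n",
        object@chrom, object@nBins, length(object@nodes),
        sum(kinds == "split"), sum(kinds == "strip"),
        max(vapply(object@nodes, function(nd) nd$rootDistance, integer(1)))
    ))
})

#' @rdname FlatClustering-class
#' @param x a `FlatClustering`.
#' @export
setMethod("clusterAssignment", "FlatClustering", function(x) x@assignment)

#' @rdname FlatClustering-class
#' @export
setMethod("nClusters", "FlatClustering", function(x) {
    length(unique(x@assignment))
})

#' @rdname FlatClustering-class
#' @export
setMethod("length", "FlatClustering", function(x) length(x@assignment))

setMethod("show", "FlatClustering", function(object) {
    cat(sprintf(
        "FlatClustering: %d loci in %d clusters\n",
        length(object@assignment), length(unique(object@assignment))
    ))
})

#' @rdname EnclaveLabels-class
#' @export
setMethod("topEnclaves", "EnclaveLabels", function(x) x@top)

#' @rdname EnclaveLabels-class
#' @export
setMethod("bottomEnclaves", "EnclaveLabels", function(x) x@bottom)

#' @rdname EnclaveLabels-class
#' @export
setMethod("treeLeaves", "EnclaveLabels", function(x) x@leaves)

setMethod("show", "EnclaveLabels", function(object) {
    cat(sprintf(
        "EnclaveLabels: %d top enclave(s), %d bottom enclave(s), %d leaves\n",
        length(object@top), length(object@bottom), length(object@leaves)
    ))
})
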