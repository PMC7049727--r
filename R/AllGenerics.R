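#' @rdname ContactMap-class
#' @param x a `ContactMap`.
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @rdname ContactMap-class
#' @export
setGeneric("contactBins", function(x) standardGeneric("contactBins"))

#' @rdname ContactMap-class
#' @export
setGeneric("mapResolution", function(x) standardGeneric("mapResolution"))

#' @rdname ContactMap-class
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname ContactMap-class
#' @export
setGeneric("mapStage", function(x) standardGeneric("mapStage"))

#' @rdname ContactMap-class
#' @export
setGeneric("droppedBins", function(x) standardGeneric("droppedBins"))

#' @rdname ContactMap-class
#' @export
setGeneric("boxcoxFit", function(x) standardGeneric("boxcoxFit"))

#' @rdname EnclaveTree-class
#' @param x an `EnclaveTree`.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname EnclaveTree-class
#' @param id node id string.
#' @export
setGeneric("getNode", function(x, id) standardGeneric("getNode"))

#' @rdname EnclaveTree-class
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))

#' @rdname FlatClustering-class
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname FlatClustering-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname EnclaveLabels-class
#' @param x an `EnclaveLabels`.
#' @export
setGeneric("topEnclaves", function(x) standardGeneric("topEnclaves"))

#' @rdname EnclaveLabels-class
#' @export
setGeneric("bottomEnclaves", function(x) standardGeneric("bottomEnclaves"))

#' @rdname EnclaveLabels-class
#' @export
setGeneric("treeLeaves", function(x) standardGeneric("treeLeaves"))

#' Spectral bisection of a weighted loci graph
#'
#' @param x a symmetric non-negative weight matrix, or a [ContactMap].
#' @param ... passed to methods; see [fiedlerBisect,matrix-method].
#' @export
setGeneric("fiedlerBisect", function(x, ...) standardGeneric("fiedlerBisect"))
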