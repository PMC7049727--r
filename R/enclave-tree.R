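#' Expansion (insulation) metric of a partition
#'
#' Ratio of the edge weight crossing from `c1` to `c2` over the edge weight
#' inside `c1`, under the literal ordered-pair convention of the defining
#' double sums: the numerator runs over `(x, y)` with `x` in `c1`, `y` in
#' `c2` (each cross edge counted once), the denominator over `(x, y)` with
#' both in `c1` (each internal edge counted twice, each diagonal once). A
#' partition with expansion `< 1` is considered insulated.
#'
#' @param w symmetric weight matrix (or [ContactMap]) on the full loci set.
#' @param c1 integer loci of the considered partition.
#' @param c2 integer loci of the partner partition from the same bisection.
#' @return the expansion value (non-negative real). If `c1` has zero
#'   internal weight the metric is undefined and an error of class
#'   `insulationUndefined` is signalled; callers treat this as "not
#'   insulated".
#' @export
expansionMetric <- function(w, c1, c2) {
    if (is(w, "ContactMap")) w <- w@matrix
    if (!length(c1) || !length(c2)) stop("c1 and c2 must be non-empty")
    if (length(intersect(c1, c2))) stop("c1 and c2 must be disjoint")
    inside <- sum(w[c1, c1])
    if (inside == 0) {
        stop(structure(
            class = c("insulationUndefined", "error", "condition"),
            list(
                message = "expansion undefined: zero internal weight",
                call = sys.call(-1)
            )
        ))
    }
    sum(w[c1, c2, drop = FALSE]) / inside
}

#' Classify a bisection as split, strip or stop
#'
#' A part is insulated iff its expansion metric is `< 1` (an undefined
#' expansion counts as not insulated). Two insulated parts make a `split`,
#' exactly one a `strip` (the insulated part is flagged), none a `stop`.
#'
#' @param w symmetric weight matrix (or [ContactMap]) on the full loci set.
#' @param bisection a list with `partA` and `partB` as returned by
#'   [fiedlerBisect()].
#' @return list with `kind` (`"split"`, `"strip"` or `"stop"`), `expansion`
#'   (named numeric for both parts, `NA` where undefined), `insulated`
#'   (named logical), and for a strip `insulatedPart` (`"A"` or `"B"`).
#' @export
classifyBisection <- function(w, bisection) {
    if (is(w, "ContactMap")) w <- w@matrix
    ex <- function(a, b) {
        tryCatch(expansionMetric(w, a, b),
            insulationUndefined = function(e) NA_real_
        )
    }
    eA <- ex(bisection$partA, bisection$partB)
    eB <- ex(bisection$partB, bisection$partA)
    ins <- c(A = isTRUE(eA < 1), B = isTRUE(eB < 1))
    kind <- c("stop", "strip", "split")[sum(ins) + 1L]
    out <- list(
        kind = kind,
        expansion = c(A = eA, B = eB),
        insulated = ins
    )
    if (kind == "strip") out$insulatedPart <- names(which(ins))
    out
}

#' Build the enclave partition tree by recursive spectral bisection
#'
#' Starting from the whole chromosome, each loci set is bisected with
#' [fiedlerBisect()] and the bisection classified with [classifyBisection()]
#' on the full-chromosome weights restricted to the two parts. Split
#' bisections recurse into both parts; strip bisections recurse only into
#' the insulated part, the partner being stored on the strip node as
#' auxiliary loci without a branch of its own. A branch terminates when its
#' loci set has at most `minLoci` members (no bisection of 2-loci sets),
#' when the bisection is classified stop, or when the bisection fails
#' numerically (the reason is recorded on the node). Every retained
#' non-root node therefore has expansion `< 1`.
#'
#' @param x a [ContactMap], normally at stage `boxcox_scaled` (any stage is
#'   accepted; a message notes unscaled input), or a plain symmetric weight
#'   matrix.
#' @param nSeedings,seed consensus 2-means parameters; all k-means seeds
#'   derive from the single master `seed` so reruns are identical.
#' @param minLoci sets with `<= minLoci` loci are not bisected (default 2).
#' @return an [EnclaveTree].
#' @export
buildEnclaveTree <- function(x, nSeedings = 5L, seed = 1234L, minLoci = 2L) {
    if (is(x, "ContactMap")) {
        if (x@stage != "boxcox_scaled") {
            message("building tree on a ", x@stage, " contact map")
        }
        w <- x@matrix
        chrom <- x@chrom
        resolution <- x@resolution
    } else {
        w <- asWeightMatrix(x)
        chrom <- "chrU"
        resolution <- 1L
    }
    n <- nrow(w)
    nodes <- list()
    newNode <- function(id, parent, loci, expansion, rootDistance) {
        list(
            id = id, parent = parent, children = character(),
            loci = sort(as.integer(loci)), auxiliary = integer(),
            expansion = expansion, branchKind = "none",
            rootDistance = as.integer(rootDistance),
            fiedlerValue = NA_real_, termination = NA_character_
        )
    }
    nodes[["R"]] <- newNode("R", NA_character_, seq_len(n), NA_real_, 0L)
    queue <- "R"
    while (length(queue)) {
        id <- queue[1]
        queue <- queue[-1]
        nd <- nodes[[id]]
        loci <- nd$loci
        if (length(loci) <= minLoci) {
            nodes[[id]]$termination <- "min_size"
            next
        }
        bis <- tryCatch(
            fiedlerBisect(w, loci = loci, nSeedings = nSeedings, seed = seed),
            error = function(e) e
        )
        if (inherits(bis, "error")) {
            nodes[[id]]$termination <-
                paste0("bisection_error: ", conditionMessage(bis))
            next
        }
        cls <- classifyBisection(w, bis)
        nodes[[id]]$fiedlerValue <- bis$fiedlerValue
        if (cls$kind == "stop") {
            nodes[[id]]$termination <- "stop"
            next
        }
        nodes[[id]]$branchKind <- cls$kind
        if (cls$kind == "split") {
            ids <- paste0(id, c(".0", ".1"))
            nodes[[ids[1]]] <- newNode(
                ids[1], id, bis$partA, cls$expansion[["A"]],
                nd$rootDistance + 1L
            )
            nodes[[ids[2]]] <- newNode(
                ids[2], id, bis$partB, cls$expansion[["B"]],
                nd$rootDistance + 1L
            )
            nodes[[id]]$children <- ids
            queue <- c(queue, ids)
        } else { # strip
            insPart <- cls$insulatedPart
            kept <- if (insPart == "A") bis$partA else bis$partB
            aux <- if (insPart == "A") bis$partB else bis$partA
            cid <- paste0(id, ".0")
            nodes[[cid]] <- newNode(
                cid, id, kept, cls$expansion[[insPart]],
                nd$rootDistance + 1L
            )
            nodes[[id]]$children <- cid
            nodes[[id]]$auxiliary <- sort(as.integer(aux))
            queue <- c(queue, cid)
        }
    }
    new("EnclaveTree",
        nodes = nodes, rootId = "R", chrom = chrom,
        resolution = as.integer(resolution), nBins = as.integer(n)
    )
}

#' Identify top enclaves, bottom enclaves and leaves
#'
#' Top enclaves are the nodes whose own bisection is a strip but above which
#' only split branchings occur ("first strips"; the root qualifies if it
#' strips immediately). Bottom enclaves are the children of split
#' branchings at or below which no further split occurs ("last splits"; a
#' split child that terminates immediately qualifies vacuously). Leaves
#' are the remaining childless nodes. A node that satisfies both the top
#' and the bottom definition (a first strip with no split below) is
#' labelled bottom — it is a last split; the three sets are disjoint and
#' every root-to-leaf path crosses at most one top and one bottom enclave.
#'
#' @param tree an [EnclaveTree].
#' @return an [EnclaveLabels].
#' @export
labelEnclaves <- function(tree) {
    nodes <- tree@nodes
    ids <- names(nodes)
    kind <- vapply(nodes, function(nd) nd$branchKind, character(1))
    parent <- vapply(nodes, function(nd) nd$parent, character(1))
    nKids <- lengths(lapply(nodes, function(nd) nd$children))

    # all ancestors are splits, computed top-down
    allSplitAbove <- stats::setNames(logical(length(ids)), ids)
    depthOrder <- ids[order(vapply(nodes, function(nd) nd$rootDistance,
        integer(1)))]
    for (id in depthOrder) {
        p <- parent[[id]]
        allSplitAbove[[id]] <- if (is.na(p)) {
            TRUE
        } else {
            allSplitAbove[[p]] && kind[[p]] == "split"
        }
    }
    # no split at or below, computed bottom-up
    noSplitAtOrBelow <- stats::setNames(logical(length(ids)), ids)
    for (id in rev(depthOrder)) {
        kids <- nodes[[id]]$children
        noSplitAtOrBelow[[id]] <- kind[[id]] != "split" &&
            all(noSplitAtOrBelow[kids])
    }

    isBottom <- vapply(ids, function(id) {
        p <- parent[[id]]
        !is.na(p) && kind[[p]] == "split" && noSplitAtOrBelow[[id]]
    }, logical(1))
    bottom <- ids[isBottom]
    top <- setdiff(ids[kind == "strip" & allSplitAbove], bottom)
    leaves <- setdiff(ids[nKids == 0L], c(top, bottom))
    new("EnclaveLabels", top = top, bottom = bottom, leaves = leaves)
}

#' Serialize an EnclaveTree to JSON
#'
#' Writes nodes with id, parent, children, branch kind, expansion, root
#' distance, termination reason, auxiliary loci and loci (1-based bin
#' indices), plus chromosome/resolution provenance. [treeFromJSON()] reads
#' the format back; a write/read round-trip is the identity.
#'
#' @param tree an [EnclaveTree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
treeToJSON <- function(tree, path) {
    obj <- list(
        chrom = tree@chrom,
        resolution = tree@resolution,
        nBins = tree@nBins,
        rootId = tree@rootId,
        nodes = unname(lapply(tree@nodes, function(nd) {
            nd$loci <- as.integer(nd$loci)
            nd$auxiliary <- as.integer(nd$auxiliary)
            nd
        }))
    )
    jsonlite::write_json(obj, path,
        auto_unbox = TRUE, digits = NA, null = "null", na = "null",
        pretty = FALSE
    )
    invisible(path)
}

#' @rdname treeToJSON
#' @export
treeFromJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    nodes <- lapply(obj$nodes, function(nd) {
        list(
            id = nd$id,
            parent = if (is.null(nd$parent)) NA_character_ else nd$parent,
            children = as.character(unlist(nd$children)),
            loci = as.integer(unlist(nd$loci)),
            auxiliary = as.integer(unlist(nd$auxiliary)),
            expansion = if (is.null(nd$expansion)) NA_real_ else
                as.numeric(nd$expansion),
            branchKind = nd$branchKind,
            rootDistance = as.integer(nd$rootDistance),
            fiedlerValue = if (is.null(nd$fiedlerValue)) NA_real_ else
                as.numeric(nd$fiedlerValue),
            termination = if (is.null(nd$termination)) NA_character_ else
                nd$termination
        )
    })
    names(nodes) <- vapply(nodes, function(nd) nd$id, character(1))
    new("EnclaveTree",
        nodes = nodes, rootId = obj$rootId, chrom = obj$chrom,
        resolution = as.integer(obj$resolution), nBins = as.integer(obj$nBins)
    )
}
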