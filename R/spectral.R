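#' Random-walk normalized graph Laplacian
#'
#' Returns `L = I - D^{-1} W`, where `D` is the diagonal degree matrix of the
#' (possibly restricted) weight matrix. The degree of a locus includes the
#' diagonal self-contact weight, so every row of `L` sums to zero. This
#' normalization corrects for highly interacting loci dominating the
#' spectrum.
#'
#' @param w symmetric non-negative weight matrix, or a [ContactMap].
#' @param loci optional integer vector of bin indices to restrict to.
#' @return the square Laplacian matrix for the restricted loci.
#' @export
randomWalkLaplacian <- function(w, loci = NULL) {
    w <- asWeightMatrix(w, loci)
    d <- rowSums(w)
    zero <- which(d <= 0)
    if (length(zero)) {
        stop("zero-degree locus in restriction: ",
            paste(rownames(w)[zero] %||% zero, collapse = ", "))
    }
    diag(nrow(w)) - w / d
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce ContactMap/matrix + loci restriction to a plain weight matrix with
# locus names preserved for error messages.
#' @noRd
asWeightMatrix <- function(w, loci = NULL) {
    if (is(w, "ContactMap")) w <- w@matrix
    stopifnot(is.matrix(w), nrow(w) == ncol(w))
    if (is.null(rownames(w))) {
        rownames(w) <- colnames(w) <- seq_len(nrow(w))
    }
    if (!is.null(loci)) w <- w[loci, loci, drop = FALSE]
    w
}

# Eigenpair for the two smallest eigenvalues of the random-walk Laplacian,
# computed through the symmetric normalized Laplacian (similarity transform:
# L_rw = D^{-1/2} L_sym D^{1/2}), so a stable symmetric solver can be used.
#' @noRd
fiedlerPair <- function(w) {
    d <- rowSums(w)
    if (any(d <= 0)) {
        stop("zero-degree locus in restriction: ",
            paste(which(d <= 0), collapse = ", "))
    }
    isq <- 1 / sqrt(d)
    lsym <- diag(nrow(w)) - (w * tcrossprod(isq))
    lsym <- (lsym + t(lsym)) / 2
    eig <- eigen(lsym, symmetric = TRUE)
    n <- nrow(w)
    ord <- n:1 # eigen() returns decreasing; smallest last
    vals <- eig$values[ord]
    if (n >= 3 && abs(vals[2] - vals[3]) < 1e-10) {
        warning("second-smallest Laplacian eigenvalue is (near-)degenerate; ",
            "the Fiedler vector is not unique")
    }
    v <- eig$vectors[, ord[2]] * isq
    # canonical sign: first locus with a non-zero coordinate is positive
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    list(value = vals[2], vector = v)
}

#' @describeIn fiedlerBisect bisect a weight matrix (optionally restricted
#'   to `loci`) by the Fiedler vector of its random-walk Laplacian, with a
#'   consensus over `nSeedings` seeded 1-D 2-means runs.
#'
#' The eigenpair of the second-smallest eigenvalue is computed through the
#' symmetric normalized Laplacian. k-means (k = 2) is run on the Fiedler
#' coordinates with `nSeedings` distinct seeds derived from `seed`; run
#' labels are aligned by ordering the cluster centers along the Fiedler
#' axis and each locus takes its majority label (ties go to the side with
#' the nearer average center). `partA` is the side with the smaller mean
#' Fiedler coordinate. The result is deterministic given `seed`, and
#' invariant to uniform rescaling of the weights.
#'
#' @param loci optional integer vector of bin indices to restrict to.
#' @param nSeedings number of seeded k-means runs entering the consensus.
#' @param seed master seed from which the k-means seeds are derived.
#' @return a list with `partA`, `partB` (disjoint non-empty integer vectors
#'   of loci, in the original indexing), `fiedlerValue` and `fiedlerVector`
#'   (named by locus).
#' @export
setMethod("fiedlerBisect", "matrix", function(x, loci = NULL, nSeedings = 5L,
                                              seed = 1234L) {
    w <- asWeightMatrix(x, loci)
    if (nrow(w) < 2L) stop("need at least 2 loci to bisect")
    lociIds <- as.integer(rownames(w))
    fp <- fiedlerPair(w)
    v <- fp$vector
    if (diff(range(v)) < 1e-12) {
        stop("degenerate split: all Fiedler coordinates identical")
    }
    lab <- consensusTwoMeans(v, nSeedings = nSeedings, seed = seed)
    list(
        partA = lociIds[lab == 1L],
        partB = lociIds[lab == 2L],
        fiedlerValue = fp$value,
        fiedlerVector = stats::setNames(v, lociIds)
    )
})

#' @rdname fiedlerBisect
#' @export
setMethod("fiedlerBisect", "ContactMap", function(x, loci = NULL,
                                                  nSeedings = 5L,
                                                  seed = 1234L) {
    fiedlerBisect(x@matrix, loci = loci, nSeedings = nSeedings, seed = seed)
})

# Consensus 2-means on 1-D coordinates: nSeedings runs with distinct seeds
# derived from the master seed; labels aligned so that cluster 1 is the one
# with the smaller center; per-point majority vote.
#' @noRd
consensusTwoMeans <- function(v, nSeedings = 5L, seed = 1234L) {
    n <- length(v)
    if (length(unique(v)) == 2L) {
        # only two distinct coordinates: the split is forced
        return(ifelse(v == min(v), 1L, 2L))
    }
    votes <- matrix(0L, n, nSeedings)
    centers <- matrix(NA_real_, 2, nSeedings)
    for (k in seq_len(nSeedings)) {
        km <- withr::with_seed(
            as.integer(seed) + k - 1L,
            stats::kmeans(v, centers = 2L, nstart = 1L, iter.max = 100L)
        )
        low <- which.min(km$centers)
        votes[, k] <- ifelse(km$cluster == low, 1L, 2L)
        centers[, k] <- sort(km$centers)
    }
    nLow <- rowSums(votes == 1L)
    lab <- ifelse(nLow * 2L > nSeedings, 1L, 2L)
    tie <- which(nLow * 2L == nSeedings)
    if (length(tie)) {
        c1 <- mean(centers[1, ]); c2 <- mean(centers[2, ])
        lab[tie] <- ifelse(abs(v[tie] - c1) <= abs(v[tie] - c2), 1L, 2L)
    }
    if (!any(lab == 1L) || !any(lab == 2L)) {
        # consensus collapsed (can only arise from pathological vote splits):
        # fall back to cutting at the largest gap
        o <- order(v)
        gap <- which.max(diff(v[o]))
        lab <- integer(n)
        lab[o[seq_len(gap)]] <- 1L
        lab[o[(gap + 1):n]] <- 2L
    }
    lab
}
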