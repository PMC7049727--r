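#' Read a sparse Hi-C triple dump into a ContactMap
#'
#' Reads the whitespace-separated `(pos_i, pos_j, count)` dialect written by
#' common Hi-C "dump" utilities (upper-triangular or full; gzip accepted) and
#' returns a symmetric, bin-indexed contact matrix. Positions are 0-based bp
#' coordinates of bin starts and must be multiples of `resolution`. Bins whose
#' total raw weight (including the diagonal) is zero correspond to unmappable
#' genomic regions and are removed; they are recorded in the `dropped` slot so
#' the original grid can be reconstructed.
#'
#' Duplicate entries for the same unordered bin pair are accepted only when
#' they agree (as produced by full symmetric dumps); conflicting duplicates
#' are an error.
#'
#' @param path path to the triple file (optionally gzip-compressed).
#' @param resolution bin width in bp.
#' @param chrom chromosome name for the bin table.
#' @return a [ContactMap] with `stage == "raw"`.
#' @examples
#' f <- tempfile()
#' writeLines(c("0 0 4", "0 50000 2", "50000 50000 6"), f)
#' cm <- readContactTriples(f, resolution = 50000, chrom = "chr1")
#' contactMatrix(cm)
#' @export
readContactTriples <- function(path, resolution, chrom) {
    resolution <- as.integer(resolution)
    stopifnot(resolution > 0L)
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    lines <- readLines(con)
    keep <- nzchar(trimws(lines))
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    lineNo <- which(keep)
    bad <- which(lengths(fields) != 3L)
    if (length(bad)) {
        stop(sprintf(
            "malformed triple at line %d: expected 3 fields, got %d",
            lineNo[bad[1]], lengths(fields)[bad[1]]
        ))
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
        ncol = 3, byrow = TRUE
    )
    nav <- which(rowSums(is.na(m)) > 0)
    if (length(nav)) {
        stop(sprintf("malformed triple at line %d: non-numeric field",
            lineNo[nav[1]]))
    }
    offGrid <- which(m[, 1] %% resolution != 0 | m[, 2] %% resolution != 0)
    if (length(offGrid)) {
        stop(sprintf(
            "position not a multiple of resolution %d at line %d",
            resolution, lineNo[offGrid[1]]
        ))
    }
    if (any(m[, 3] < 0)) {
        stop("negative contact counts are not allowed")
    }

    i <- as.integer(m[, 1] %/% resolution)
    j <- as.integer(m[, 2] %/% resolution)
    # canonicalize to upper triangle, then resolve duplicates
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
        rng <- tapply(m[, 3], key, function(v) diff(range(v)))
        if (any(rng > 0)) {
            stop("conflicting duplicate entries for the same bin pair")
        }
        first <- !duplicated(key)
        lo <- lo[first]; hi <- hi[first]
        val <- m[first, 3]
    } else {
        val <- m[, 3]
    }

    nAll <- max(hi) + 1L
    w <- matrix(0, nAll, nAll)
    w[cbind(lo + 1L, hi + 1L)] <- val
    w[cbind(hi + 1L, lo + 1L)] <- val

    keepBin <- rowSums(w) > 0
    if (sum(keepBin) < 2L) {
        stop("degenerate input: fewer than 2 retained bins")
    }
    starts0 <- (seq_len(nAll) - 1L) * resolution
    mkBins <- function(sel) {
        GenomicRanges::GRanges(
            seqnames = rep(chrom, sum(sel)),
            ranges = IRanges::IRanges(
                start = starts0[sel] + 1L,
                width = rep(resolution, sum(sel))
            )
        )
    }
    bins <- mkBins(keepBin)
    bins$binId <- seq_len(sum(keepBin))
    dropped <- mkBins(!keepBin)

    new("ContactMap",
        matrix = w[keepBin, keepBin, drop = FALSE],
        bins = bins,
        resolution = resolution,
        chrom = chrom,
        stage = "raw",
        dropped = dropped,
        meta = list()
    )
}

#' Write a ContactMap as sparse upper-triangular triples
#'
#' Writes the non-zero upper-triangular entries (including the diagonal) in
#' the same `(pos_i, pos_j, value)` dialect [readContactTriples()] consumes.
#' Positions are the 0-based start coordinates of the retained bins, so a
#' write/read round-trip reproduces the matrix on the retained grid.
#'
#' @param x a [ContactMap].
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
writeContactTriples <- function(x, path) {
    stopifnot(is(x, "ContactMap"))
    w <- x@matrix
    starts0 <- GenomicRanges::start(x@bins) - 1L
    idx <- which(upper.tri(w, diag = TRUE) & w != 0, arr.ind = TRUE)
    df <- data.frame(
        i = starts0[idx[, 1]],
        j = starts0[idx[, 2]],
        v = w[idx]
    )
    df <- df[order(df$i, df$j), ]
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    utils::write.table(df, con,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Write the bin table of a ContactMap as BED
#'
#' Columns: chrom, start (0-based), end (exclusive), binId.
#' @param x a [ContactMap].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBinsBed <- function(x, path) {
    stopifnot(is(x, "ContactMap"))
    b <- x@bins
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(b)),
        start = GenomicRanges::start(b) - 1L,
        end = GenomicRanges::end(b),
        name = b$binId
    )
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Knight-Ruiz-style matrix balancing
#'
#' Balances a raw contact matrix by symmetric diagonal scaling
#' `diag(s) %*% W %*% diag(s)` so that all row sums equal 1, correcting
#' locus-specific coverage bias (enzymatic digestion frequency). The scaling
#' vector is found by the symmetric Sinkhorn-Knopp fixed-point iteration
#' `s <- sqrt(s / (W s))`, which converges to the same balanced matrix as a
#' Newton-type Knight-Ruiz solver on matrices with positive row sums.
#'
#' @param x a [ContactMap] with `stage == "raw"`.
#' @param tol convergence tolerance: the maximum absolute deviation of the
#'   balanced row sums from 1 (relative to 1).
#' @param maxIter maximum number of iterations.
#' @return a [ContactMap] with `stage == "kr_normalized"`; the scaling vector
#'   is stored in `meta$krScaling`.
#' @export
krBalance <- function(x, tol = 1e-8, maxIter = 1000L) {
    stopifnot(is(x, "ContactMap"))
    if (x@stage != "raw") {
        stop("krBalance expects a raw-stage ContactMap, got ", x@stage)
    }
    w <- x@matrix
    rs <- rowSums(w)
    if (any(rs == 0)) {
        stop("zero row encountered: bin(s) ",
            paste(which(rs == 0), collapse = ", "))
    }
    s <- 1 / sqrt(rs)
    resid <- Inf
    for (it in seq_len(maxIter)) {
        ws <- as.vector(w %*% s)
        resid <- max(abs(s * ws - 1))
        if (resid < tol) break
        s <- sqrt(s / ws)
    }
    if (resid >= tol) {
        stop(sprintf(
            "KR balancing did not converge in %d iterations (residual %.3g)",
            maxIter, resid
        ))
    }
    bal <- w * tcrossprod(s)
    bal <- (bal + t(bal)) / 2 # remove round-off asymmetry
    initialize(x,
        matrix = bal, stage = "kr_normalized",
        meta = c(x@meta, list(krScaling = s, krResidual = resid))
    )
}

#' Box-Cox scaling of a balanced contact matrix
#'
#' Selects the chromosome-specific Box-Cox exponent maximizing the profile
#' log-likelihood for normality of the strictly positive contact weights
#' (via the standard maximum-likelihood procedure of \pkg{MASS}), then
#' transforms positive entries by `(x^lambda - 1) / lambda` (or `log(x)` at
#' `lambda == 0`). Structural zeros encode absent contacts and stay zero.
#'
#' Because downstream spectral clustering needs non-negative edge weights,
#' when any transformed value is negative all transformed positive-support
#' entries are shifted by `-min + eps` (an epsilon-scale constant), which
#' preserves their ordering; zeros remain zero. The applied shift is recorded
#' in `meta$boxcoxShift`.
#'
#' @param x a [ContactMap] with `stage == "kr_normalized"` (set
#'   `force = TRUE` to scale another stage).
#' @param lambdaGrid grid of candidate exponents for the profile likelihood.
#' @param force allow stages other than `kr_normalized`.
#' @return a [ContactMap] with `stage == "boxcox_scaled"`; the fit (selected
#'   `lambda` plus the `(lambda, logLik)` profile) is available via
#'   [boxcoxFit()].
#' @export
boxcoxScale <- function(x, lambdaGrid = seq(-2, 2, by = 0.05), force = FALSE) {
    stopifnot(is(x, "ContactMap"))
    if (!force && x@stage != "kr_normalized") {
        stop("boxcoxScale expects a kr_normalized ContactMap, got ", x@stage,
            " (use force = TRUE to override)")
    }
    w <- x@matrix
    ut <- upper.tri(w, diag = TRUE)
    vals <- w[ut & w > 0]
    if (!length(vals)) {
        stop("degenerate input: no positive contact weights to scale")
    }
    lambda <- fitBoxcoxLambda(vals, lambdaGrid)
    fit <- attr(lambda, "profile")
    lambda <- as.numeric(lambda)

    pos <- w > 0
    tw <- w
    tw[pos] <- boxcoxTransform(w[pos], lambda)
    shift <- 0
    if (any(tw[pos] < 0)) {
        shift <- -min(tw[pos]) + sqrt(.Machine$double.eps)
        tw[pos] <- tw[pos] + shift
    }
    tw <- (tw + t(tw)) / 2
    initialize(x,
        matrix = tw, stage = "boxcox_scaled",
        meta = c(x@meta, list(
            boxcox = list(
                lambda = lambda,
                profile = fit
            ),
            boxcoxShift = shift
        ))
    )
}

#' @noRd
boxcoxTransform <- function(v, lambda) {
    if (lambda == 0) log(v) else (v^lambda - 1) / lambda
}

# Profile-likelihood lambda on a positive sample; returns lambda with the
# evaluated grid attached. Delegates the profile to MASS::boxcox.
#' @noRd
fitBoxcoxLambda <- function(vals, lambdaGrid) {
    prof <- MASS::boxcox(vals ~ 1,
        lambda = lambdaGrid, plotit = FALSE, interp = FALSE
    )
    best <- which.max(prof$y)
    structure(prof$x[best],
        profile = data.frame(lambda = prof$x, logLik = prof$y)
    )
}
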