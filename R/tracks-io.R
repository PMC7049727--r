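#' Read a genomic feature track (BED / narrowPeak)
#'
#' BED columns 1-3 are required; for narrowPeak the ENCODE extra columns
#' are parsed and `signalValue` is used as the site intensity. Strand is
#' ignored throughout (Hi-C bins are unstranded).
#'
#' @param path path to the track file.
#' @param format `"bed"` or `"narrowPeak"` (default guessed from the file
#'   extension).
#' @return a [GenomicRanges::GRanges].
#' @export
readFeatureTrack <- function(path, format = NULL) {
    if (is.null(format)) {
        format <- if (grepl("narrowPeak(\\.gz)?$", path, ignore.case = TRUE)) {
            "narrowPeak"
        } else {
            "bed"
        }
    }
    format <- match.arg(format, c("bed", "narrowPeak"))
    gr <- if (format == "narrowPeak") {
        rtracklayer::import(path,
            format = "BED",
            extraCols = c(
                signalValue = "numeric", pValue = "numeric",
                qValue = "numeric", peak = "integer"
            )
        )
    } else {
        rtracklayer::import(path, format = "BED")
    }
    GenomicRanges::strand(gr) <- "*"
    gr
}

#' Read a reference clustering from labelled BED
#'
#' Reads a BED file whose 4th column carries a cluster label (e.g. TAD or
#' compartment ids) and converts it to a [FlatClustering] on the bin grid
#' of a contact map: each bin takes the label of the interval with the
#' largest bp overlap; bins overlapped by no interval go to the catch-all
#' cluster.
#'
#' @param path path to the labelled BED file.
#' @param bins bin table ([GenomicRanges::GRanges] with `binId`).
#' @param unassignedLabel catch-all label for uncovered bins.
#' @return a [FlatClustering] over the bins.
#' @export
readReferenceClustering <- function(path, bins,
                                    unassignedLabel = "unclustered") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name)) {
        stop("reference BED needs a label in column 4")
    }
    referenceClustering(gr, bins, unassignedLabel)
}

#' @rdname readReferenceClustering
#' @param intervals labelled intervals as GRanges with a `name` column.
#' @export
referenceClustering <- function(intervals, bins,
                                unassignedLabel = "unclustered") {
    assignment <- rep(unassignedLabel, length(bins))
    hits <- GenomicRanges::findOverlaps(bins, intervals, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(q)) {
        w <- GenomicRanges::width(GenomicRanges::pintersect(
            bins[q], intervals[s], ignore.strand = TRUE
        ))
        o <- order(q, -w)
        first <- !duplicated(q[o])
        assignment[bins$binId[q[o][first]]] <-
            as.character(intervals$name[s[o][first]])
    }
    FlatClustering(assignment)
}

#' Read DNA loops from BEDPE
#'
#' Parses the 6 required BEDPE columns (chrom1, start1, end1, chrom2,
#' start2, end2; further columns ignored) into a pair of anchor GRanges.
#' No installed package reads BEDPE, so the parser lives here.
#'
#' @param path path to the BEDPE file (optionally gzip-compressed).
#' @return a [S4Vectors::Pairs] of two GRanges (anchor 1, anchor 2).
#' @export
readLoops <- function(path) {
    df <- utils::read.table(path,
        sep = "\t", header = FALSE,
        stringsAsFactors = FALSE, comment.char = "#"
    )
    if (ncol(df) < 6) {
        stop("BEDPE needs at least 6 columns, got ", ncol(df))
    }
    mk <- function(chr, s, e) {
        GenomicRanges::GRanges(chr, IRanges::IRanges(
            start = as.integer(s) + 1L,
            end = as.integer(e)
        ))
    }
    S4Vectors::Pairs(
        mk(df[[1]], df[[2]], df[[3]]),
        mk(df[[4]], df[[5]], df[[6]])
    )
}

#' Write DNA loops as BEDPE
#'
#' @param loops a [S4Vectors::Pairs] of two GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLoops <- function(loops, path) {
    a1 <- S4Vectors::first(loops)
    a2 <- S4Vectors::second(loops)
    df <- data.frame(
        chrom1 = as.character(GenomicRanges::seqnames(a1)),
        start1 = GenomicRanges::start(a1) - 1L,
        end1 = GenomicRanges::end(a1),
        chrom2 = as.character(GenomicRanges::seqnames(a2)),
        start2 = GenomicRanges::start(a2) - 1L,
        end2 = GenomicRanges::end(a2)
    )
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}

#' Write a feature track as BED or narrowPeak text
#'
#' Tracks carrying a `signalValue` column are written as 10-column ENCODE
#' narrowPeak (placeholders for p/q-value and peak offset), others as
#' 6-column BED.
#'
#' @param track a GRanges, optionally with `signalValue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTrack <- function(track, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(track)),
        start = GenomicRanges::start(track) - 1L,
        end = GenomicRanges::end(track),
        name = if (!is.null(track$name)) track$name else ".",
        score = 0L,
        strand = "."
    )
    if (!is.null(track$signalValue)) {
        df$signalValue <- track$signalValue
        df$pValue <- -1
        df$qValue <- -1
        df$peak <- -1L
    }
    utils::write.table(df, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE
    )
    invisible(path)
}
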