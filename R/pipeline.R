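#' Assemble a pipeline run configuration
#'
#' Defaults reproduce the method's stated constants: 5 k-means seedings per
#' bisection, 500 random clusterings for the VI null, KR tolerance 1e-8,
#' Box-Cox grid \[-2, 2\] in steps of 0.05, FDR 0.05, master seed 1234.
#'
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @param seed master seed for every source of randomness.
#' @param triples path to a sparse triple dump (alternatively `simulate`).
#' @param simulate list of arguments for [simulateContactMap()] to run on
#'   synthetic data instead of an input file.
#' @param outDir output directory.
#' @param skipKr,skipBoxcox skip the corresponding prep stage.
#' @param krTol,krMaxIter KR balancing controls.
#' @param lambdaGrid Box-Cox lambda grid.
#' @param nSeedings k-means seedings per bisection.
#' @param draws random clusterings for the VI null.
#' @param fdrLevel Benjamini-Hochberg FDR level for enrichment tests.
#' @param referenceBed optional labelled BED reference clustering.
#' @param trackFile optional feature track (BED/narrowPeak).
#' @param metric overlap metric for the enrichment analysis.
#' @param loopsFile optional BEDPE loops.
#' @return a named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(resolution = 50000L, chrom = "chrS",
                           seed = 1234L, triples = NULL, simulate = NULL,
                           outDir = tempfile("hicenclave_run_"),
                           skipKr = FALSE, skipBoxcox = FALSE,
                           krTol = 1e-8, krMaxIter = 1000L,
                           lambdaGrid = seq(-2, 2, by = 0.05),
                           nSeedings = 5L, draws = 500L, fdrLevel = 0.05,
                           referenceBed = NULL, trackFile = NULL,
                           metric = "count", loopsFile = NULL) {
    structure(
        list(
            resolution = as.integer(resolution), chrom = chrom,
            seed = as.integer(seed), triples = triples, simulate = simulate,
            outDir = outDir, skipKr = skipKr, skipBoxcox = skipBoxcox,
            krTol = krTol, krMaxIter = as.integer(krMaxIter),
            lambdaGrid = lambdaGrid, nSeedings = as.integer(nSeedings),
            draws = as.integer(draws), fdrLevel = fdrLevel,
            referenceBed = referenceBed, trackFile = trackFile,
            metric = metric, loopsFile = loopsFile
        ),
        class = "pipelineConfig"
    )
}

#' Run the full per-chromosome pipeline
#'
#' Executes the requested stages in order — input (file or simulation),
#' KR balancing, Box-Cox scaling, tree construction, enclave labelling and
#' nestedness, then optionally VI validation against a reference
#' clustering, feature-enrichment analysis and DNA-loop integration — and
#' writes each product plus a provenance manifest (package version, seed,
#' parameters, input checksums) into `config$outDir`. Identical
#' configuration and inputs give identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory products (`map`, `tree`,
#'   `labels`, `ns`, and when requested `vi`, `enrichment`, `loops`) and
#'   the `manifest`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outDir, f)
    checksums <- list()

    if (!is.null(config$simulate)) {
        sim <- do.call(simulateContactMap, config$simulate)
        map <- sim$map
    } else {
        if (is.null(config$triples) || !file.exists(config$triples)) {
            stop("input triples file not found (set 'triples' or 'simulate')")
        }
        checksums$triples <- unname(tools::md5sum(config$triples))
        map <- readContactTriples(config$triples, config$resolution,
            config$chrom)
        sim <- NULL
    }
    if (!config$skipKr) {
        map <- krBalance(map, tol = config$krTol, maxIter = config$krMaxIter)
    }
    if (!config$skipBoxcox) {
        map <- boxcoxScale(map, lambdaGrid = config$lambdaGrid,
            force = config$skipKr)
    }
    writeContactTriples(map, out("matrix.tsv"))
    writeBinsBed(map, out("bins.bed"))

    tree <- suppressMessages(buildEnclaveTree(map,
        nSeedings = config$nSeedings, seed = config$seed
    ))
    treeToJSON(tree, out("tree.json"))
    labels <- labelEnclaves(tree)
    ns <- nestedness(tree, labels)
    nestednessToBed(ns, contactBins(map), out("nestedness.bed"))

    results <- list(map = map, tree = tree, labels = labels, ns = ns)
    if (!is.null(sim)) results$truthClustering <- sim$clustering

    if (!is.null(config$referenceBed)) {
        checksums$reference <- unname(tools::md5sum(config$referenceBed))
        ref <- readReferenceClustering(config$referenceBed, contactBins(map))
        vi <- viSignificance(tree, ref,
            draws = config$draws,
            seed = config$seed, labels = labels
        )
        viDf <- data.frame(
            chrom = config$chrom, observed_vi = vi$observedVi,
            null_mean = mean(vi$nullVis), null_sd = stats::sd(vi$nullVis),
            r = vi$r, n = vi$n, p = vi$p
        )
        utils::write.table(viDf, out("vi.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
        )
        results$vi <- vi
    }
    if (!is.null(config$trackFile)) {
        checksums$track <- unname(tools::md5sum(config$trackFile))
        track <- readFeatureTrack(config$trackFile)
        fe <- featureEnrichment(tree, labels, ns, contactBins(map), track,
            metric = config$metric
        )
        utils::write.table(fe, out("fe.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
        )
        results$enrichment <- fe
        results$enrichmentTests <- nestednessEnrichmentTests(fe)
        utils::write.table(results$enrichmentTests, out("fe_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
        )
    }
    if (!is.null(config$loopsFile)) {
        checksums$loops <- unname(tools::md5sum(config$loopsFile))
        loops <- readLoops(config$loopsFile)
        li <- loopIntegration(
            loops, enclaveClustering(tree, labels), contactBins(map)
        )
        utils::write.table(li$perLoop, out("loops.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
        )
        results$loops <- li
    }

    manifest <- list(
        package = "HiCenclave",
        version = as.character(utils::packageVersion("HiCenclave")),
        rVersion = as.character(getRversion()),
        date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = config$seed,
        simulated = !is.null(config$simulate),
        parameters = config[setdiff(
            names(config),
            c("triples", "referenceBed", "trackFile", "loopsFile", "outDir",
              "simulate")
        )],
        inputChecksums = checksums
    )
    jsonlite::write_json(manifest, out("manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    results$manifest <- manifest
    invisible(results)
}
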