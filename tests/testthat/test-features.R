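test_that("overlap summaries reproduce the defining substitutions", {
    # cluster of two 5 kb bins (bp_cl = 10 000)
    cluster <- grIv(c(1, 10001), c(5000, 15000))
    site <- grIv(4001, 5000) # 1000 bp inside the cluster
    site$signalValue <- 3.0
    expect_equal(overlapSummary(cluster, site, "size")$value, 0.1)
    expect_equal(overlapSummary(cluster, site, "intensity")$value, 0.3)
    # 3 sites of which 2 intersect (any overlap length)
    track <- grIv(c(4001, 14951, 70001), c(5000, 16000, 70100))
    expect_equal(overlapSummary(cluster, track, "count")$value, 2)
})

test_that("intensity metric demands an intensity column", {
    cluster <- grIv(1, 1000)
    track <- grIv(10, 20)
    expect_error(
        overlapSummary(cluster, track, "intensity"),
        "intensity"
    )
})

test_that("interval arithmetic agrees with the naive pairwise oracle", {
    for (seed in 1:50) {
        fix <- withr::with_seed(seed + 3000, {
            nS <- sample(5:20, 1)
            nC <- sample(2:6, 1)
            s <- sort(sample(1:5000, nS))
            cs <- sort(sample(seq(1, 5000, by = 500), nC))
            list(
                siteStart = s, siteEnd = s + sample(50:800, nS, replace = TRUE),
                clStart = cs, clEnd = cs + 499,
                intensity = stats::runif(nS, 0.5, 4)
            )
        })
        track <- grIv(fix$siteStart, fix$siteEnd)
        track$signalValue <- fix$intensity
        cluster <- grIv(fix$clStart, fix$clEnd)
        ov <- bruteOverlapBp(fix$siteStart, fix$siteEnd, fix$clStart,
            fix$clEnd)
        bpCl <- sum(fix$clEnd - fix$clStart + 1)
        expect_equal(
            overlapSummary(cluster, track, "size")$value,
            sum(ov) / bpCl,
            tolerance = 1e-12
        )
        expect_equal(
            overlapSummary(cluster, track, "intensity")$value,
            sum(ov * fix$intensity) / bpCl,
            tolerance = 1e-12
        )
        expect_equal(
            overlapSummary(cluster, track, "count")$value,
            sum(ov > 0)
        )
    }
})

test_that("size overlaps are conserved over a partition of the chromosome", {
    # bp-weighted mean of per-cluster size fractions over a partition equals
    # the genome-wide coverage fraction of the track
    fx <- sharedPipelineFixture()
    bins <- contactBins(fx$map)
    track <- simulateFeatureTrack(bins, seed = 5, baseRate = 2)
    cl <- enclaveClustering(fx$tree, fx$labels)
    a <- clusterAssignment(cl)
    tot <- 0
    for (lab in unique(a)) {
        cb <- bins[a[bins$binId] == lab]
        s <- overlapSummary(cb, track, "size")
        tot <- tot + s$value * s$bpCl
    }
    expect_equal(
        tot / sum(GenomicRanges::width(bins)),
        overlapSummary(bins, track, "size")$value,
        tolerance = 1e-12
    )
})

test_that("feature enrichment is the ratio to the top-enclave mean", {
    fx <- sharedPipelineFixture()
    bins <- contactBins(fx$map)
    track <- simulateFeatureTrack(bins, seed = 13, baseRate = 3)
    fe <- featureEnrichment(fx$tree, fx$labels, fx$ns, bins, track)
    ok <- !is.na(fe$fe)
    expect_true(any(ok))
    # FE averages to 1 within each top enclave by construction
    for (id in unique(stats::na.omit(fe$topEnclave))) {
        sel <- fe$topEnclave == id & !is.na(fe$topEnclave)
        if (any(sel & ok)) {
            expect_equal(mean(fe$fe[sel]), 1, tolerance = 1e-12)
        }
        # and the ratio definition holds locus-wise
        m <- mean(fe$value[sel])
        expect_equal(fe$fe[sel], fe$value[sel] / m, tolerance = 1e-12)
    }
    # loci outside every top enclave are excluded
    expect_true(all(is.na(fe$fe[is.na(fe$topEnclave)])))
})

test_that("constant overlap counts give FE = 1", {
    fx <- sharedPipelineFixture()
    bins <- contactBins(fx$map)
    # one site per bin, fully inside it
    track <- grIv(GenomicRanges::start(bins) + 10,
        GenomicRanges::start(bins) + 109)
    fe <- featureEnrichment(fx$tree, fx$labels, fx$ns, bins, track)
    sel <- !is.na(fe$fe)
    expect_true(all(abs(fe$fe[sel] - 1) < 1e-12))
})

test_that("the exact Poisson rate test matches a direct tail computation", {
    # observed rate equal to expected: ratio 1, p ~ 1
    r <- poissonRatioTest(10, 10, 1)
    expect_equal(r$rateRatio, 1)
    expect_gt(r$p, 0.99)
    # observed 20 where expectation is 10
    r2 <- poissonRatioTest(20, 10, 1)
    expect_equal(r2$rateRatio, 2)
    expect_equal(r2$p, brutePoissonTwoSided(20, 10), tolerance = 1e-10)
    # brute tails across many scenarios
    for (seed in 1:50) {
        cfg <- withr::with_seed(seed + 7000, {
            list(x = sample(0:40, 1), t = stats::runif(1, 2, 30),
                rate = stats::runif(1, 0.2, 2))
        })
        expect_equal(
            poissonRatioTest(cfg$x, cfg$t, cfg$rate)$p,
            brutePoissonTwoSided(cfg$x, cfg$t * cfg$rate),
            tolerance = 1e-10
        )
    }
    # doubling both observed and exposure keeps the ratio
    expect_equal(
        poissonRatioTest(20, 10, 1)$rateRatio,
        poissonRatioTest(40, 20, 1)$rateRatio
    )
    # zero expected rate with non-zero observed is degenerate-significant
    dz <- poissonRatioTest(3, 10, 0)
    expect_equal(dz$p, 0)
    expect_true(dz$degenerate)
})

test_that("the FE significance threshold is 75th percentile + 2 IQR", {
    u <- withr::with_seed(31, stats::runif(10000))
    expect_equal(feSignificanceThreshold(u), 1.75, tolerance = 0.02)
    # degenerate constant null: IQR 0, threshold c
    expect_equal(suppressWarnings(feSignificanceThreshold(rep(2.5, 10))), 2.5)
    # permutation invariance
    x <- withr::with_seed(32, stats::rlnorm(100))
    expect_equal(
        feSignificanceThreshold(x),
        feSignificanceThreshold(withr::with_seed(33, sample(x)))
    )
    expect_warning(feSignificanceThreshold(stats::runif(10)), "fewer than 20")
})

test_that("loop integration counts anchors in a shared enclave", {
    bins <- grIv(seq(1, 10000, by = 1000), seq(1000, 10000, by = 1000))
    bins$binId <- 1:10
    cl <- FlatClustering(c(rep("e1", 4), rep("e2", 4), "unclustered",
        "unclustered"))
    mkLoop <- function(s1, s2) {
        list(grIv(s1, s1 + 99), grIv(s2, s2 + 99))
    }
    l <- list(
        mkLoop(101, 3101), # both in e1 -> integrated
        mkLoop(101, 4101), # e1 and e2 -> not integrated
        mkLoop(4201, 6201) # both in e2 -> integrated
    )
    loops <- S4Vectors::Pairs(
        do.call(c, lapply(l, `[[`, 1)),
        do.call(c, lapply(l, `[[`, 2))
    )
    li <- loopIntegration(loops, cl, bins)
    expect_equal(li$percent, 100 * 2 / 3, tolerance = 1e-10)
    expect_identical(li$perLoop$integrated, c(TRUE, FALSE, TRUE))
    # an anchor spanning two enclaves goes to the larger bp overlap
    span <- grIv(3800, 4500) # 200 bp in e1 (bin 4), 500 bp in e2 (bin 5)
    loops2 <- S4Vectors::Pairs(span, grIv(5101, 5200))
    li2 <- loopIntegration(loops2, cl, bins)
    expect_identical(li2$perLoop$anchor1, "e2")
    expect_true(li2$perLoop$integrated)
    # anchors on unclustered loci never integrate
    loops3 <- S4Vectors::Pairs(grIv(8101, 8200), grIv(9101, 9200))
    expect_equal(loopIntegration(loops3, cl, bins)$percent, 0)
})

test_that("enrichment tests flag a planted signal and not a null track", {
    fx <- sharedPipelineFixture()
    bins <- contactBins(fx$map)
    ns <- fx$ns$perLocus$ns
    target <- which(!is.na(ns) & ns > stats::median(ns, na.rm = TRUE))
    track <- simulateFeatureTrack(bins, targetLoci = target,
        enrichment = 10, baseRate = 0.5, seed = 21)
    fe <- featureEnrichment(fx$tree, fx$labels, fx$ns, bins, track)
    ok <- !is.na(fe$fe) & !is.na(fe$ns)
    ct <- suppressWarnings(
        stats::cor.test(fe$ns[ok], fe$fe[ok], method = "spearman",
            alternative = "greater")
    )
    expect_lt(ct$p.value, 0.01)
    tests <- nestednessEnrichmentTests(fe)
    expect_true(any(tests$padj < 0.05))
    # a uniform track shows no systematic signal
    null <- simulateFeatureTrack(bins, enrichment = 1, baseRate = 0.5,
        seed = 22)
    feN <- featureEnrichment(fx$tree, fx$labels, fx$ns, bins, null)
    testsN <- nestednessEnrichmentTests(feN)
    expect_true(all(testsN$padj >= 0.05))
})
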