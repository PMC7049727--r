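test_that("expansion metric follows the ordered-pair convention", {
    # hand-enumerated toy: w(a,b) = 3 inside C1 = {a,b}, single cross edge
    # w(b,c) = 2 to C2 = {c}; ordered denominator 6, numerator 2 -> 1/3
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 3
    w[2, 3] <- w[3, 2] <- 2
    expect_equal(expansionMetric(w, c(1, 2), 3), 1 / 3)
    # internally connected part with no crossing edges -> 0
    w2 <- matrix(0, 4, 4)
    w2[1, 2] <- w2[2, 1] <- 5
    w2[3, 4] <- w2[4, 3] <- 5
    expect_equal(expansionMetric(w2, c(1, 2), c(3, 4)), 0)
})

test_that("expansion agrees with the brute-force double loop", {
    for (seed in 1:50) {
        n <- withr::with_seed(seed, sample(5:8, 1))
        w <- randomWeightMatrix(n, seed + 500)
        c1 <- withr::with_seed(seed, sample(n, sample(2:(n - 2), 1)))
        c2 <- setdiff(seq_len(n), c1)
        expect_equal(
            expansionMetric(w, c1, c2),
            bruteExpansion(w, c1, c2),
            tolerance = 1e-12
        )
    }
})

test_that("zero internal weight is an insulation-undefined condition", {
    w <- matrix(0, 3, 3)
    w[1, 3] <- w[3, 1] <- 1
    w[2, 3] <- w[3, 2] <- 1
    expect_error(
        expansionMetric(w, c(1, 2), 3),
        class = "insulationUndefined"
    )
})

test_that("bisections classify as split, strip or stop", {
    # two disconnected cliques -> both expansions 0 -> split
    w <- matrix(0, 6, 6)
    w[1:3, 1:3] <- 1
    w[4:6, 4:6] <- 1
    diag(w) <- 0
    cls <- classifyBisection(w, list(partA = 1:3, partB = 4:6))
    expect_identical(cls$kind, "split")
    expect_equal(unname(cls$expansion), c(0, 0))

    # dense clique plus an appendage interacting mostly with the clique
    w <- matrix(0, 6, 6)
    w[1:4, 1:4] <- 2
    diag(w) <- 0
    w[5, 1:4] <- w[1:4, 5] <- 1
    w[6, 1:4] <- w[1:4, 6] <- 1
    w[5, 6] <- w[6, 5] <- 0.1
    cls <- classifyBisection(w, list(partA = 1:4, partB = 5:6))
    expect_identical(cls$kind, "strip")
    expect_identical(cls$insulatedPart, "A")
    expect_equal(
        unname(cls$expansion["A"]),
        bruteExpansion(w, 1:4, 5:6)
    )
    expect_gt(cls$expansion[["B"]], 1)

    # complete bipartite graph with negligible internal weight -> stop
    w <- matrix(0, 6, 6)
    w[1:3, 4:6] <- 1
    w <- w + t(w)
    w[1, 2] <- w[2, 1] <- 1e-3
    w[4, 5] <- w[5, 4] <- 1e-3
    cls <- classifyBisection(w, list(partA = 1:3, partB = 4:6))
    expect_identical(cls$kind, "stop")

    # undefined expansion counts as not insulated
    w0 <- matrix(0, 4, 4)
    w0[1:2, 3:4] <- 1
    w0 <- w0 + t(w0)
    w0[3, 4] <- w0[4, 3] <- 5
    cls <- classifyBisection(w0, list(partA = 1:2, partB = 3:4))
    expect_identical(cls$kind, "strip")
    expect_true(is.na(cls$expansion[["A"]]))
})

test_that("the recursion recovers a planted two-level split hierarchy", {
    # 4 blocks in 2 superblocks with strong within-block weights: the first
    # two tree levels must be splits recovering superblocks then blocks
    h <- plantedHierarchy(list(
        plantedBlock("S1", 1:32, 40, list(
            plantedBlock("A", 1:16, 60), plantedBlock("B", 17:32, 60)
        )),
        plantedBlock("S2", 33:64, 40, list(
            plantedBlock("C", 33:48, 60), plantedBlock("D", 49:64, 60)
        ))
    ))
    sim <- simulateContactMap(h, nBins = 64, seed = 3)
    map <- boxcoxScale(krBalance(sim$map))
    tree <- suppressMessages(buildEnclaveTree(map))
    root <- getNode(tree, "R")
    expect_identical(root$branchKind, "split")
    supers <- lapply(root$children, function(id) getNode(tree, id))
    got <- sort(vapply(supers, function(nd) paste(range(nd$loci),
        collapse = "-"), character(1)))
    expect_identical(got, c("1-32", "33-64"))
    for (nd in supers) {
        expect_identical(nd$branchKind, "split")
        blocks <- lapply(nd$children, function(id) sort(getNode(tree, id)$loci))
        truthBlocks <- if (1 %in% nd$loci) {
            list(1:16, 17:32)
        } else {
            list(33:48, 49:64)
        }
        expect_true(all(vapply(blocks, function(b) {
            any(vapply(truthBlocks, identical, logical(1), x = b))
        }, logical(1))))
    }
})

test_that("tiny and structureless inputs terminate the recursion", {
    # 3 loci: at most one bisection, children terminate at <= 2 loci
    w <- matrix(c(0, 5, 1, 5, 0, 1, 1, 1, 0), 3)
    tree <- buildEnclaveTree(w, seed = 1)
    for (id in nodeIds(tree)) {
        nd <- getNode(tree, id)
        if (length(nd$children) == 0) {
            expect_lte(length(nd$loci), 3)
            expect_true(!is.na(nd$termination))
        }
        expect_lte(nd$rootDistance, 1)
    }
    # uniform weights: no insulated structure anywhere
    wu <- matrix(1, 10, 10)
    diag(wu) <- 0
    wu <- wu + withr::with_seed(8, {
        e <- matrix(stats::runif(100, 0, 1e-6), 10)
        (e + t(e)) / 2
    })
    treeU <- suppressWarnings(buildEnclaveTree(wu, seed = 1))
    nonRoot <- setdiff(nodeIds(treeU), "R")
    for (id in nonRoot) {
        expect_lt(getNode(treeU, id)$expansion, 1)
    }
    # uniform weights admit no split: for a bisection into sizes n1, n2 the
    # ordered-pair expansions are ~ n2/(n1 - 1) and n1/(n2 - 1), which can
    # never both be below 1, so only strips and stops occur
    kinds <- vapply(nodeIds(treeU), function(id) {
        getNode(treeU, id)$branchKind
    }, character(1))
    expect_false(any(kinds == "split"))
    # and the stored expansions agree with the brute-force oracle
    for (id in nonRoot) {
        nd <- getNode(treeU, id)
        parent <- getNode(treeU, nd$parent)
        partner <- if (parent$branchKind == "split") {
            getNode(treeU, setdiff(parent$children, id))$loci
        } else {
            parent$auxiliary
        }
        expect_equal(nd$expansion, bruteExpansion(wu, nd$loci, partner),
            tolerance = 1e-12)
    }
})

test_that("every retained non-root node is insulated and splits partition", {
    fx <- sharedPipelineFixture()
    tree <- fx$tree
    w <- contactMatrix(fx$map)
    for (id in nodeIds(tree)) {
        nd <- getNode(tree, id)
        if (id != "R") {
            expect_lt(nd$expansion, 1)
            # stored expansion equals the brute-force value of this node
            # against its bisection partner
            parent <- getNode(tree, nd$parent)
            partner <- if (parent$branchKind == "split") {
                sib <- setdiff(parent$children, id)
                getNode(tree, sib)$loci
            } else {
                parent$auxiliary
            }
            expect_equal(nd$expansion, bruteExpansion(w, nd$loci, partner),
                tolerance = 1e-10)
        }
        if (nd$branchKind == "split") {
            kids <- lapply(nd$children, function(k) getNode(tree, k)$loci)
            expect_length(intersect(kids[[1]], kids[[2]]), 0)
            expect_identical(sort(c(kids[[1]], kids[[2]])), nd$loci)
        }
        if (nd$branchKind == "strip") {
            kid <- getNode(tree, nd$children)$loci
            expect_identical(sort(c(kid, nd$auxiliary)), nd$loci)
        }
    }
})

test_that("tree JSON serialization round-trips and is seed-stable", {
    fx <- sharedPipelineFixture()
    f1 <- withr::local_tempfile()
    f2 <- withr::local_tempfile()
    treeToJSON(fx$tree, f1)
    back <- treeFromJSON(f1)
    # structure round-trips exactly; floating-point fields to 1e-12
    for (id in nodeIds(fx$tree)) {
        a <- getNode(back, id)
        b <- getNode(fx$tree, id)
        expect_identical(a[c("id", "parent", "children", "loci",
            "auxiliary", "branchKind", "rootDistance", "termination")],
            b[c("id", "parent", "children", "loci", "auxiliary",
                "branchKind", "rootDistance", "termination")])
        expect_equal(a$expansion, b$expansion, tolerance = 1e-12)
    }
    expect_identical(back@rootId, fx$tree@rootId)
    # rebuilding with the same seed gives byte-identical JSON
    tree2 <- suppressMessages(buildEnclaveTree(fx$map))
    treeToJSON(tree2, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("a non-contiguous planted block is kept whole in one node", {
    # the defining enclave property: a planted block split into two distant
    # genomic intervals must appear as a single tree node
    fx <- sharedPipelineFixture()
    truth <- clusterAssignment(fx$sim$clustering)
    distantLoci <- which(truth == "S3a")
    gaps <- diff(sort(distantLoci))
    expect_gt(max(gaps), 10) # genuinely split into distant intervals
    hit <- Filter(function(id) {
        setequal(getNode(fx$tree, id)$loci, distantLoci)
    }, nodeIds(fx$tree))
    expect_gte(length(hit), 1)
})
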