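mkAS <- function(starts, ends, chrom = "chrSim") {
    GRanges(chrom, IRanges(start = starts + 1L, end = ends), state = "AS")
}
mkGenes <- function(starts, ends, strands, expr, chrom = "chrSim") {
    if (length(starts) == 0L) {
        gr <- GRanges()
        mcols(gr)$expression <- numeric(0)
        return(gr)
    }
    GRanges(chrom, IRanges(start = starts + 1L, end = ends),
            strand = strands, expression = expr)
}

test_that("AS typing follows the bounded-intergap and flank rules", {
    ## AS fully inside an intergap bounded by two flanking active genes
    ## (both strictly within 20 kb): type 1
    genes <- mkGenes(c(5000, 75000), c(25000, 95000), c("-", "+"), c(5, 5))
    expect_identical(classifyASTypes(mkAS(40000, 60000), genes), 1L)
    ## one active gene within 20 kb on one side only: type 2
    genes2 <- mkGenes(0, 20000, "-", 5)
    expect_identical(classifyASTypes(mkAS(25000, 45000), genes2), 2L)
    ## nearest active gene 50 kb away: type 3
    expect_identical(classifyASTypes(mkAS(70000, 90000), genes2), 3L)
    ## two flanking active genes but the AS mostly outside their intergap:
    ## falls through to type 4
    genes4 <- mkGenes(c(30000, 60000), c(50000, 80000), c("+", "+"),
                      c(5, 5))
    expect_identical(classifyASTypes(mkAS(20000, 58000), genes4), 4L)
    ## inactive genes do not rescue typing: type 3
    genes5 <- mkGenes(c(5000, 75000), c(25000, 95000), c("-", "+"), c(0, 0))
    expect_identical(classifyASTypes(mkAS(40000, 60000), genes5), 3L)
    ## distant bounding genes without flanking contact stay type 3
    far <- mkGenes(c(0, 480000), c(20000, 500000), c("-", "+"), c(5, 5))
    expect_identical(classifyASTypes(mkAS(240000, 260000), far), 3L)
})

test_that("typing is exhaustive and exclusive on random layouts", {
    set.seed(71)
    for (i in 1:20) {
        nA <- 5L
        s <- sort(sample(seq(0, 9e5, by = 1000), nA))
        as <- mkAS(s, s + 20000)
        ng <- sample(0:6, 1)
        gs <- sort(sample(seq(0, 9.5e5, by = 500), ng))
        genes <- if (ng) mkGenes(gs, gs + 15000,
                                 sample(c("+", "-"), ng, TRUE),
                                 sample(c(0, 10), ng, TRUE))
                 else mkGenes(integer(0), integer(0), character(0),
                              numeric(0))
        ty <- classifyASTypes(as, genes)
        expect_identical(length(ty), nA)
        expect_true(all(ty %in% 1:4))
    }
})

test_that("typing matches the generator's construction labels", {
    cfg <- simulationConfig(4e6, zones = makeZones(4e6, 8), nCells = 10)
    placements <- c("both", "left", "none", "right", "both",
                    "inactive-both", "none", "both")
    genes <- generateGeneAnnotation(cfg, cfg$zones, placements = placements)
    zones <- mkAS(cfg$zones$start, cfg$zones$end)
    expect_identical(classifyASTypes(zones, genes),
                     metadata(genes)$expectedType)
})

test_that("nearest gene distances are signed and zero inside genes", {
    genes <- mkGenes(12500, 30000, "+", 5)
    d <- nearestGeneDistances(mkAS(5000, 10000), genes)
    ## right AS end at 10,000; active gene starts at 12,500
    right <- d[d$side == "right" & d$class == "active", ]
    expect_equal(right$distance, 2500)
    ## AS end inside a gene: distance 0
    d2 <- nearestGeneDistances(mkAS(5000, 15000), genes)
    expect_equal(d2[d2$side == "right" & d2$class == "active",
                    "distance"], 0)
    ## no inactive gene anywhere: unassigned
    expect_true(all(is.na(d$distance[d$class == "inactive"])))
    ## fixture distances equal the generator's gap by construction
    cfg <- simulationConfig(2e6, zones = makeZones(2e6, 2), nCells = 10)
    genes2 <- generateGeneAnnotation(cfg, cfg$zones, placements = "both",
                                     gap = 10000)
    dz <- nearestGeneDistances(mkAS(cfg$zones$start, cfg$zones$end), genes2)
    act <- dz[dz$class == "active", ]
    expect_true(all(abs(act$distance) == 10000))
})

test_that("segment shuffling conserves lengths and alternation", {
    set.seed(72)
    starts <- c(10000, 50000, 120000, 300000)
    ends <- c(30000, 90000, 150000, 340000)
    for (i in 1:50) {
        sh <- shuffleSegments(starts, ends, 4e5)
        expect_identical(sort(sh$end - sh$start), sort(ends - starts))
        o <- order(sh$start)
        expect_true(all(sh$start[o][-1] >= sh$end[o][-4]))
        expect_gte(min(sh$start), 0)
        expect_lte(max(sh$end), 4e5)
        ## leading gap is preserved
        expect_equal(min(sh$start), 10000)
    }
})

test_that("uniformly placed genes fall inside the shuffle-null band", {
    set.seed(73)
    n <- 12L
    s <- seq(50000, 950000, length.out = n)
    as <- mkAS(s, s + 25000)
    mcols(as)$timingClass <- rep(c("S1", "S2"), each = n / 2)
    regions <- GRanges("chrSim", IRanges(c(1, 500001), c(500000, 1000000)),
                       timingClass = c("S1", "S2"))
    gs <- sort(runif(15, 0, 9.6e5))
    genes <- mkGenes(gs, gs + 12000, sample(c("+", "-"), 15, TRUE),
                     rep(10, 15))
    out <- shuffleNull(as, regions, genes, nSims = 200, seed = 99)
    obs <- out$observed[out$observed$class == "active", "count"]
    lo <- out$null[out$null$class == "active", "lo"]
    hi <- out$null[out$null$class == "active", "hi"]
    ## same number of distances overall, and most bins inside the band
    expect_equal(sum(obs),
                 sum(out$null[out$null$class == "active", "mean"]),
                 tolerance = 1e-6)
    expect_gte(mean(obs >= lo & obs <= hi), 0.8)
    expect_identical(out$flaggedClasses, character(0))
    ## a singleton timing class is passed through and flagged
    mcols(as)$timingClass <- c("S1", rep("S2", n - 1))
    out2 <- shuffleNull(as, regions, genes, nSims = 5, seed = 1)
    expect_identical(out2$flaggedClasses, "S1")
})

test_that("intergap orientation and overlap classification", {
    ## three genes: - + then + -, giving a divergent and a convergent gap
    genes <- mkGenes(c(0, 50000, 120000), c(20000, 70000, 140000),
                     c("-", "+", "-"), c(5, 5, 5))
    as <- mkAS(30000, 45000)    # overlaps only the first (divergent) gap
    tab <- intergeneInitiation(as, genes, sizeBreaks = c(0, Inf))
    div <- tab[tab$orientation == "divergent", ]
    conv <- tab[tab$orientation == "tandem" |
                tab$orientation == "convergent", ]
    expect_equal(div$proportion, 1)
    expect_equal(sum(conv$proportion), 0)
    ## an intergap entirely covered by an AS counts as overlapping
    wide <- mkAS(10000, 130000)
    tab2 <- intergeneInitiation(wide, genes, sizeBreaks = c(0, Inf))
    expect_true(all(tab2$proportion == 1))
})

test_that("RFD groups by gene orientation and activity", {
    ## genome with RFD fixed at +1
    sbc <- countsFromVectors(rep(0L, 60), rep(100L, 60), chrom = "chrSim")
    p <- computeRFD(sbc, windowSize = 5000, maskThreshold = 0)
    genes <- mkGenes(c(10000, 40000), c(20000, 50000), c("+", "-"),
                     c(5, 0))
    out <- rfdTranscriptionCoorientation(p, genes)
    expect_equal(unname(out$means["rightward"]), 1)
    expect_equal(unname(out$means["inactive"]), 1)
    expect_true(is.na(out$means["leftward"]))
    ## without genes everything is intergenic
    none <- rfdTranscriptionCoorientation(p, genes[0])
    expect_equal(sum(none$histograms[, "intergene"]), sum(!isMasked(p)))
    expect_true(all(none$groups == "intergene"))
    ## opposite-strand overlapping genes exclude their windows
    ov <- mkGenes(c(10000, 12000), c(30000, 32000), c("+", "-"), c(5, 5))
    out2 <- rfdTranscriptionCoorientation(p, ov)
    expect_gt(out2$nExcluded, 0)
})

test_that("co-orientation emerges when zones sit at rightward gene heads", {
    ## rightward genes immediately downstream of efficient zones
    cfg <- simulationConfig(2e6, zones = makeZones(2e6, 4,
        firingProbability = 0.9), nCells = 250, readDepth = 80, seed = 77)
    truth <- simulateReplication(cfg)
    counts <- sampleOkSeqReads(truth)[[1]]
    p <- computeRFD(counts)
    genes <- generateGeneAnnotation(cfg, cfg$zones, placements = "right",
                                    orientations = "divergent",
                                    geneLength = 60000, gap = 5000)
    out <- rfdTranscriptionCoorientation(p, genes)
    expect_gt(unname(out$means["rightward"]), 0.2)
})

test_that("high-|RFD| flat segments report co-oriented gene context", {
    mk <- function(meanR) {
        W <- as.integer(round(rep(100 * (1 - meanR) / 2, 40)))
        C <- as.integer(round(rep(100 * (1 + meanR) / 2, 40)))
        countsFromVectors(W, C, chrom = "chrSim")
    }
    p <- computeRFD(mk(0.9), windowSize = 5000, maskThreshold = 0)
    seg <- GRanges("chrSim", IRanges(10001, 30000), state = "FS",
                   rfdStart = NA_real_, rfdEnd = NA_real_,
                   efficiency = NA_real_, meanAbsRFD = NA_real_,
                   highRFD = NA, timingClass = NA_character_)
    ss <- new("SegmentSet", segments = seg, windowSize = 5000L,
              step = 1000L)
    genes <- mkGenes(10000, 25000, "+", 5)   # TSS at the FS start
    st <- highRfdFsStats(ss, p, genes)
    expect_identical(nrow(st), 1L)
    expect_identical(st$direction, "+")
    expect_equal(st$dCoLeft, 0)              # co-oriented TSS at the end
    expect_gt(st$covCo, 0.7)
    ## |RFD| = 0.5 is below the unidirectionality cutoff: not flagged
    p5 <- computeRFD(mk(0.5), windowSize = 5000, maskThreshold = 0)
    expect_identical(nrow(highRfdFsStats(ss, p5, genes)), 0L)
})

test_that("feature enrichment is normalized to the regional average", {
    anchors <- GRanges("chrSim", IRanges(c(100001, 300001), width = 30000))
    ## all features exactly at anchor left borders: a spike at 0
    feats <- GRanges("chrSim", IRanges(c(100001, 300001), width = 1))
    prof <- featureEnrichment(feats, anchors, span = 20000,
                              binWidth = 2000)
    expect_equal(mean(prof$density), 1, tolerance = 1e-9)
    expect_identical(which.max(prof$density), which(prof$position > 0 &
                                                    prof$position < 2000))
    expect_equal(sum(prof$density > 0), 1L)
    ## rescaled mode with uniform coverage is flat at 1
    set.seed(81)
    mids <- unlist(lapply(c(100001, 300001), function(s)
        s + seq(750, 29250, by = 1500)))
    un <- GRanges("chrSim", IRanges(mids, width = 1))
    rp <- featureEnrichment(un, anchors, rescale = TRUE, nBins = 10)
    expect_equal(rp$density, rep(1, 10))
    ## empty features warn and return zeros
    expect_warning(z <- featureEnrichment(feats[0], anchors, span = 10000),
                   "all-zero")
    expect_true(all(z$density == 0))
})

test_that("anchor overlap fraction profiles peak at reference points", {
    anchors <- GRanges("chrSim", IRanges(seq(1, 9e5, by = 1e5),
                                         width = 30000))
    refs <- GRanges("chrSim", IRanges(seq(1, 9e5, by = 1e5), width = 1))
    prof <- overlapFractionProfile(anchors, refs, span = 3e5,
                                   binWidth = 1e5)
    atZero <- prof$fraction[prof$offset == 50000]
    expect_equal(atZero, 1)
})

test_that("directionality index follows the reconstructed chi-square form", {
    expect_equal(directionalityIndex(10, 10), 0)
    expect_equal(directionalityIndex(0, 20), 20)     # E=10, DI=+20
    expect_equal(directionalityIndex(20, 0), -20)
    expect_equal(directionalityIndex(0, 0), 0)
    ## antisymmetry under A/B exchange
    set.seed(82)
    A <- rpois(50, 30); B <- rpois(50, 30)
    expect_equal(directionalityIndex(A, B), -directionalityIndex(B, A))
    expect_error(directionalityIndex(-1, 5), "non-negative")
})

test_that("nested same-strand genes are removed before analysis", {
    genes <- mkGenes(c(0, 5000, 40000), c(30000, 10000, 60000),
                     c("+", "+", "-"), c(5, 5, 5))
    clean <- cleanGeneAnnotation(genes)
    expect_identical(length(clean), 2L)
    expect_false(any(start(clean) == 5001))
    ## opposite-strand nesting is kept
    genes2 <- mkGenes(c(0, 5000), c(30000, 10000), c("+", "-"), c(5, 5))
    expect_identical(length(cleanGeneAnnotation(genes2)), 2L)
})
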