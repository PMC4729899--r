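test_that("a single always-firing zone forces the RFD geometry", {
    cfg <- simulationConfig(1e6,
        zones = data.frame(start = 485000, end = 515000,
                           firingProbability = 1, timeMean = 30,
                           timeSd = 10),
        backgroundRate0 = 0, nCells = 100, readDepth = 50, seed = 5)
    truth <- simulateReplication(cfg)
    r <- trueRFD(truth)
    expect_true(all(r[1:480] == -1))          # left of the zone: leftward
    expect_true(all(r[520:1000] == 1))        # right of the zone: rightward
    inside <- r[486:515]
    expect_true(all(diff(inside) >= 0))       # linear ramp across the zone
    expect_true(all(is.finite(trueMRT(truth))))
    ## conservation: every bin of every cell replicated exactly once
    expect_true(all(truth@rightCount >= 0 & truth@rightCount <= 100))
    dirs <- cellForkDirections(truth, 1)
    expect_length(dirs, 1000)
    expect_true(all(dirs %in% c("rightward", "leftward")))
    ## with one cell, right + left indicators sum to the bin count
    cfg1 <- simulationConfig(1e6, zones = cfg$zones, backgroundRate0 = 0,
                             nCells = 1, readDepth = 50, seed = 5)
    t1 <- simulateReplication(cfg1)
    expect_identical(sum(t1@rightCount) + sum(1 - t1@rightCount), 1000)
})

test_that("two equidistant always-firing zones terminate at the midpoint", {
    zones <- data.frame(start = c(45000, 345000), end = c(55000, 355000),
                        firingProbability = 1, timeMean = 30, timeSd = 10)
    cfg <- simulationConfig(4e5, zones = zones, backgroundRate0 = 0,
                            nCells = 10000, readDepth = 1, seed = 21)
    truth <- simulateReplication(cfg)
    r <- trueRFD(truth)
    ## brute-force average over 10,000 cells: RFD crosses 0 at the midpoint
    mid <- 200    # bin index of 200 kb
    expect_lt(abs(r[mid]), 0.05)
    expect_gt(mean(r[120:180]), 0.5)
    expect_lt(mean(r[220:280]), -0.5)
    crossing <- which(diff(sign(r[100:300])) < 0) + 99
    expect_true(any(abs(crossing - mid) <= 10))
})

test_that("sampled read counts converge to the true strand fractions", {
    cfg <- simulationConfig(2e5,
        zones = data.frame(start = 95000, end = 105000,
                           firingProbability = 0.6, timeMean = 30,
                           timeSd = 15),
        nCells = 400, readDepth = 10000, nReplicates = 1, seed = 9)
    truth <- simulateReplication(cfg)
    counts <- sampleOkSeqReads(truth)[[1]]
    C <- crickCounts(counts); W <- watsonCounts(counts)
    emp <- (C - W) / (C + W)
    err <- abs(emp - trueRFD(truth))
    ## law of large numbers: per-bin error is O(1/sqrt(depth))
    expect_lt(unname(quantile(err, 0.95)), 0.02)
    expect_lt(max(err), 0.05)
    ## pure rightward bins emit no Watson reads in expectation
    pure <- trueRFD(truth) == 1
    if (any(pure)) expect_true(all(W[pure] == 0))
    expect_error(sampleOkSeqReads(truth,
        simulationConfig(2e5, zones = cfg$zones, readDepth = -1)),
        "readDepth")
})

test_that("replicates from the same truth correlate strongly", {
    sim <- smallSimulation()
    p1 <- computeRFD(sim$reps[[1]])
    p2 <- computeRFD(sim$reps[[2]])
    rc <- replicateCorrelation(p1, p2)
    expect_gt(rc$correlation, 0.9)
    expect_gt(rc$nShared, 1000)
})

test_that("zone firing statistics recover the configured probability", {
    sim <- smallSimulation(nCells = 300)
    zs <- zoneStats(sim$truth)
    p <- sim$cfg$zones$firingProbability
    ## scheduled firing is Bernoulli(p): within 3 binomial SE
    se <- sqrt(p * (1 - p) / 300)
    expect_true(all(abs(zs$nScheduled / 300 - p) <= pmax(3 * se, 0.01)))
    ## realized firing can only be reduced by passive replication
    expect_true(all(zs$nRealized <= zs$nScheduled))
})

test_that("simulated Repli-seq enrichments are per-bin time distributions", {
    sim <- smallSimulation(nCells = 80)
    tp <- simulateRepliSeq(sim$truth)
    en <- enrichmentMatrix(tp)
    expect_equal(rowSums(en), rep(1, nrow(en)), tolerance = 1e-12)
    expect_true(all(en >= 0))
    ## a bin always replicated at the same S-phase fraction concentrates
    ## its enrichment in the corresponding compartment
    cfg <- simulationConfig(1e5,
        zones = data.frame(start = 0, end = 1000, firingProbability = 1,
                           timeMean = 50, timeSd = 0),
        backgroundRate0 = 0, nCells = 30, readDepth = 1, seed = 2)
    tr <- simulateReplication(cfg)
    tp2 <- simulateRepliSeq(tr)
    lastBin <- enrichmentMatrix(tp2)[100, ]
    expect_equal(unname(lastBin[6]), 1)       # replicated last, always
})

test_that("cells without any initiation are rejected and resampled", {
    cfg <- simulationConfig(1e5,
        zones = data.frame(start = 50000, end = 60000,
                           firingProbability = 0, timeMean = 30, timeSd = 10),
        backgroundRate0 = 0, nCells = 2, readDepth = 1, seed = 3)
    expect_error(simulateReplication(cfg), "zero initiation")
    ## overlapping zones are a config error
    expect_error(simulationConfig(1e5,
        zones = data.frame(start = c(0, 5000), end = c(10000, 20000),
                           firingProbability = 1, timeMean = 1, timeSd = 1)),
        "non-overlapping")
    expect_error(simulationConfig(1e5, zones = makeZones(1e5, 1),
                                  forkSpeed = 0), "forkSpeed")
})

test_that("the cascade of background firing yields an N-shaped gradient", {
    ## two distant efficient zones, exponentially growing background:
    ## the population RFD decreases from the left zone to the midpoint
    zones <- data.frame(start = c(50000, 1550000), end = c(80000, 1580000),
                        firingProbability = 1, timeMean = 20, timeSd = 10)
    cfg <- simulationConfig(1.6e6, zones = zones, backgroundRate0 = 2e-5,
                            backgroundGrowth = 0.015, nCells = 5000,
                            readDepth = 1, seed = 13)
    truth <- simulateReplication(cfg)
    r <- trueRFD(truth)
    ## block means between right zone edge (80 kb) and midpoint (815 kb):
    ## non-increasing up to finite-population noise, with a strict drop
    ## while the gradient is steep and a null plateau at the midpoint
    blocks <- split(r[81:815], rep(1:7, each = 105))
    m <- vapply(blocks, mean, 0)
    expect_true(all(diff(m) <= 0.02))
    expect_true(all(diff(m[1:3]) < 0))
    expect_gt(m[1], 0.6)
    expect_lt(abs(mean(r[790:840])), 0.2)     # ~0 at the midpoint
})

test_that("gene annotation fixtures encode their construction", {
    cfg <- simulationConfig(3e6, zones = makeZones(3e6, 6), nCells = 10)
    genes <- generateGeneAnnotation(cfg, cfg$zones,
        placements = c("both", "left", "none", "right", "inactive-both",
                       "both"),
        orientations = "divergent")
    expect_identical(metadata(genes)$expectedType,
                     c(1L, 2L, 3L, 2L, 3L, 1L))
    ## "both" placements contribute two genes, "left"/"right" one, others 0/2
    expect_identical(length(genes), 2L + 1L + 0L + 1L + 2L + 2L)
    expect_true(all(mcols(genes)$expression[mcols(genes)$placement ==
                                            "inactive-both"] == 0))
    ## divergent placement: left gene on -, right gene on +
    g1 <- genes[mcols(genes)$zone == 1]
    expect_identical(as.character(strand(g1)), c("-", "+"))
    ## genes that do not fit are a config error
    expect_error(generateGeneAnnotation(cfg, data.frame(
        start = 5000, end = 35000, firingProbability = 1, timeMean = 1,
        timeSd = 1), placements = "both", geneLength = 50000), "fit")
})
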