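test_that("RFD increments follow the half-difference formula", {
    sbc <- countsFromVectors(W = c(40L, 40L, 30L, 30L, 20L),
                             C = c(60L, 60L, 70L, 70L, 80L))
    p <- computeRFD(sbc, windowSize = 1000, maskThreshold = 0)
    tr <- deltaRFD(p)
    expect_equal(tr@delta, diff(rfd(p)) / 2)
    ## RFD 0.2 then 0.4 gives increment 0.1
    p2 <- computeRFD(countsFromVectors(W = c(40L, 30L), C = c(60L, 70L)),
                     windowSize = 1000, maskThreshold = 0)
    expect_equal(deltaRFD(p2)@delta, 0.1)
    ## constant profile: all increments zero
    pc <- computeRFD(countsFromVectors(rep(10L, 8), rep(30L, 8)),
                     windowSize = 1000, maskThreshold = 0)
    expect_true(all(deltaRFD(pc)@delta == 0))
    ## linear ramp -1 to +1 over 30 windows: constant increment 1/29
    W <- as.integer(round(seq(1000, 0, length.out = 30)))
    C <- 1000L - W
    pr <- computeRFD(countsFromVectors(W, C), windowSize = 1000,
                     maskThreshold = 0)
    expect_equal(deltaRFD(pr)@delta, rep(1 / 29, 29), tolerance = 0.02)
})

test_that("quantile coding splits increments into five equal classes", {
    tr <- DeltaRFDTrack("chr1", 0:4 * 1000, delta = c(-2, -1, 0, 1, 2))
    expect_identical(quantileEncode(tr)@code, 1:5)
    ## all-equal increments: degenerate median coding with a warning
    tre <- DeltaRFDTrack("chr1", 0:5 * 1000, delta = rep(0.3, 6))
    expect_warning(enc <- quantileEncode(tre), "degenerate")
    expect_true(all(enc@code == 3L))
    ## each code holds n/5 +- 1 elements on continuous data
    set.seed(31)
    trn <- DeltaRFDTrack("chr1", (0:999) * 1000, delta = rnorm(1000))
    tab <- table(quantileEncode(trn)@code)
    expect_true(all(abs(tab - 200) <= 1))
    expect_error(quantileEncode(DeltaRFDTrack("chr1", 0:2 * 1000,
                                              delta = c(1, 2, NA))),
                 "at least 5")
})

test_that("Viterbi decoding matches exhaustive path enumeration", {
    params <- defaultHMMParameters()
    set.seed(41)
    lengths <- c(2:8, 10)
    for (n in lengths) {
        for (rep in 1:3) {
            obs <- sample(1:5, n, replace = TRUE)
            if (rep == 3 && n > 3) obs[2] <- NA   # missing observation
            dec <- hmmDecode(trackFromCodes(obs))
            oracle <- enumeratePaths(obs, params)
            expect_equal(pathLogProb(dec$state, obs, params),
                         oracle$maxLogProb, tolerance = 1e-9)
            if (oracle$nTied == 1L)
                expect_identical(dec$state, oracle$path)
        }
    }
})

test_that("decoding is symmetric under profile negation", {
    set.seed(42)
    obs <- sample(1:5, 200, replace = TRUE, prob = c(.1, .2, .4, .2, .1))
    obs[30:45] <- sample(4:5, 16, replace = TRUE)
    obs[100:115] <- sample(1:2, 16, replace = TRUE)
    d1 <- hmmDecode(trackFromCodes(obs))$state
    d2 <- hmmDecode(trackFromCodes(6L - obs))$state
    swap <- c(Up = "Down", Down = "Up", Flat1 = "Flat2", Flat2 = "Flat1")
    expect_identical(unname(swap[d1]), d2)
})

test_that("decoded paths recover planted state blocks", {
    ## all observations at the median code decode to a flat state
    flat <- hmmDecode(trackFromCodes(rep(3L, 50)))$state
    expect_true(all(flat %in% c("Flat1", "Flat2")))
    ## twenty high codes then twenty low codes: an Up run then a Down run
    path <- hmmDecode(trackFromCodes(c(rep(5L, 20), rep(1L, 20))))$state
    expect_true(all(path[1:20] == "Up"))
    expect_true(all(path[21:40] == "Down"))
    ## non-stochastic parameters are rejected
    bad <- defaultHMMParameters()
    bad$transition[1, 1] <- 0.5
    expect_error(hmmDecode(trackFromCodes(rep(3L, 10)), params = bad),
                 "sum to 1")
})

test_that("long masked runs split decoding, short ones are bridged", {
    obs <- c(rep(5L, 30), rep(NA, 5), rep(5L, 30))
    d <- hmmDecode(trackFromCodes(obs), gapMax = 100000)
    expect_false(anyNA(d$state))              # 5 kb gap bridged
    d2 <- hmmDecode(trackFromCodes(obs), gapMax = 3000)
    expect_true(all(is.na(d2$state[31:35])))  # gap longer than gapMax
    expect_false(anyNA(d2$state[c(1:30, 36:65)]))
})

test_that("state runs convert to contiguous tiling segments", {
    sbc <- countsFromVectors(rep(50L, 6), rep(50L, 6))
    p <- computeRFD(sbc, windowSize = 1000, maskThreshold = 0)
    path <- data.frame(chrom = "chr1", position = (0:4) * 1000,
                       state = c("Up", "Up", "Up", "Down", "Down"))
    ss <- segmentsFromStates(path, p)
    gr <- segmentRanges(ss)
    expect_identical(as.character(mcols(gr)$state), c("AS", "DS"))
    expect_identical(start(gr) - 1L, c(0L, 3000L))
    expect_identical(end(gr), c(3000L, 5000L))   # contiguous, half-open
    ## all-flat path: single FS spanning the track
    path2 <- data.frame(chrom = "chr1", position = (0:4) * 1000,
                        state = c("Flat1", "Flat1", "Flat2", "Flat2",
                                  "Flat2"))
    ss2 <- segmentsFromStates(path2, p)
    expect_identical(as.character(mcols(segmentRanges(ss2))$state), "FS")
    expect_identical(width(segmentRanges(ss2)), 5000L)
})

test_that("ascending-segment efficiency is half the RFD shift in percent", {
    ## left plateau RFD -0.1, right plateau RFD +0.3 -> efficiency 20%
    nb <- 30L
    rfdL <- -0.1; rfdR <- 0.3
    W <- as.integer(round(c(rep(1000 * (1 - rfdL) / 2, nb),
                            rep(1000 * (1 - rfdR) / 2, nb))))
    C <- as.integer(round(c(rep(1000 * (1 + rfdL) / 2, nb),
                            rep(1000 * (1 + rfdR) / 2, nb))))
    sbc <- countsFromVectors(W, C)
    p <- computeRFD(sbc, windowSize = 1000, maskThreshold = 0)
    ## the ascending run must span the plateau transition at 30 kb so that
    ## its 5-kb end windows sit cleanly on either plateau
    path <- data.frame(chrom = "chr1",
                       position = seq(25000, 34000, by = 1000),
                       state = "Up")
    ss <- segmentsFromStates(path, p, counts = sbc, endWindow = 5000)
    expect_equal(efficiencies(ss), 100 * (rfdR - rfdL) / 2, tolerance = 0.5)
    ## full inversion corresponds to 100%; masked ends stay unassigned
    expect_equal(100 * (1 - (-1)) / 2, 100)
    ssm <- segmentEfficiency(ss, sbc, endWindow = 5000,
                             maskThreshold = 10000L)
    expect_true(is.na(efficiencies(ssm)))
})

test_that("only reproducible segments survive replicate retention", {
    mkset <- function(starts, ends, states) {
        gr <- GRanges("chr1", IRanges(start = starts + 1L, end = ends),
                      state = states, rfdStart = NA_real_,
                      rfdEnd = NA_real_, efficiency = NA_real_,
                      meanAbsRFD = NA_real_, highRFD = NA,
                      timingClass = NA_character_)
        new("SegmentSet", segments = gr, windowSize = 15000L, step = 1000L)
    }
    s1 <- mkset(c(0, 50000), c(30000, 80000), c("AS", "DS"))
    ## identical sets: everything retained with unchanged coordinates
    r <- retainReproducible(s1, s1)
    expect_identical(granges(segmentRanges(r)), granges(segmentRanges(s1)))
    ## disjoint sets: nothing retained
    s2 <- mkset(c(200000), c(230000), "AS")
    expect_identical(length(segmentRanges(retainReproducible(s1, s2))), 0L)
    ## same locus, different state: dropped from both
    s3 <- mkset(c(0, 50000), c(30000, 80000), c("DS", "AS"))
    expect_identical(length(segmentRanges(retainReproducible(s1, s3))), 0L)
    ## partial overlap below the reciprocal threshold: dropped
    s4 <- mkset(c(20000, 50000), c(50000, 80000), c("AS", "DS"))
    r4 <- retainReproducible(s1, s4, minRecip = 0.5)
    expect_identical(as.character(mcols(segmentRanges(r4))$state), "DS")
    ## coordinates of retained pairs are the intersection
    s5 <- mkset(c(10000, 50000), c(40000, 80000), c("AS", "DS"))
    r5 <- retainReproducible(s1, s5, minRecip = 0.5)
    asr <- segmentRanges(r5)[mcols(segmentRanges(r5))$state == "AS"]
    expect_identical(c(start(asr) - 1L, end(asr)), c(10000L, 30000L))
})

test_that("a planted zone is recovered as an ascending segment", {
    cfg <- simulationConfig(2e6,
        zones = data.frame(start = 985000, end = 1015000,
                           firingProbability = 1, timeMean = 40,
                           timeSd = 15),
        nCells = 300, readDepth = 150, seed = 23)
    truth <- simulateReplication(cfg)
    counts <- sampleOkSeqReads(truth)[[1]]
    ss <- segmentsOf(counts)
    asr <- segmentRanges(ss)[segmentStates(ss) == "AS"]
    zone <- GRanges("chrSim", IRanges(985001, 1015000))
    ov <- findOverlaps(zone, asr)
    expect_gt(length(ov), 0)
    best <- subjectHits(ov)[which.max(width(pintersect(
        rep(zone, length(ov)), asr[subjectHits(ov)])))]
    jacc <- width(pintersect(zone, asr[best])) /
        width(punion(zone, asr[best]))
    expect_gt(jacc, 0.6)
})
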