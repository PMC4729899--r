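suppressMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(Biostrings)
})

## Independent oracle: score every one of the 4^n state paths by direct
## accumulation of log transition/emission terms, entirely apart from the
## dynamic-programming recursion under test. Returns the maximal log
## probability and one argmax path.
enumeratePaths <- function(obs, params) {
    S <- length(params$states)
    n <- length(obs)
    logT <- log(params$transition)
    logE <- log(params$emission)
    emis <- function(t) if (is.na(obs[t])) numeric(S) else logE[, obs[t]]
    scores <- log(params$initial) + emis(1L)   # one entry per path so far
    last <- seq_len(S)
    for (t in seq_len(n)[-1L]) {
        k <- length(scores)
        scores <- rep(scores, times = S) +
            logT[cbind(rep(last, times = S), rep(seq_len(S), each = k))] +
            rep(emis(t), each = k)
        last <- rep(seq_len(S), each = k)
    }
    best <- which.max(scores)
    ## decode mixed-radix path index: position t is digit t (base S)
    idx <- best - 1L
    path <- integer(n)
    for (t in seq_len(n)) {
        path[t] <- idx %% S + 1L
        idx <- idx %/% S
    }
    list(maxLogProb = scores[best], path = params$states[path],
         nTied = sum(abs(scores - scores[best]) < 1e-12))
}

## Log probability of a given state path (for comparing against the oracle).
pathLogProb <- function(stateNames, obs, params) {
    s <- match(stateNames, params$states)
    logT <- log(params$transition)
    logE <- log(params$emission)
    lp <- log(params$initial[s[1L]]) +
        (if (is.na(obs[1L])) 0 else logE[s[1L], obs[1L]])
    for (t in seq_along(s)[-1L]) {
        lp <- lp + logT[s[t - 1L], s[t]] +
            (if (is.na(obs[t])) 0 else logE[s[t], obs[t]])
    }
    lp
}

## Independent oracle: RFD of a genomic span straight from raw stranded
## read positions (no binning).
rfdFromReads <- function(reads, spanStart, spanEnd) {
    sel <- reads$position >= spanStart & reads$position < spanEnd
    C <- sum(reads$strand[sel] == "-")
    W <- sum(reads$strand[sel] == "+")
    (C - W) / (C + W)
}

## Small deterministic stranded counts: one chromosome, explicit W/C.
countsFromVectors <- function(W, C, binSize = 1000L, chrom = "chr1") {
    StrandedBinCounts(chrom, (seq_along(W) - 1L) * binSize, W = W, C = C,
                      binSize = binSize)
}

## Quantile-coded track straight from a code vector.
trackFromCodes <- function(codes, step = 1000L, chrom = "chr1") {
    DeltaRFDTrack(chrom, (seq_along(codes) - 1L) * step,
                  code = codes, step = step)
}

## A small two-replicate simulation shared by several tests.
smallSimulation <- function(seed = 7L, nCells = 150L, readDepth = 80,
                            genomeLength = 2e6, nZones = 4L,
                            firingProbability = c(0.4, 0.7, 1, 0.5)) {
    cfg <- simulationConfig(genomeLength,
                            zones = makeZones(genomeLength, nZones,
                                firingProbability = firingProbability),
                            nCells = nCells, readDepth = readDepth,
                            seed = seed)
    truth <- simulateReplication(cfg)
    list(cfg = cfg, truth = truth, reps = sampleOkSeqReads(truth))
}

segmentsOf <- function(counts, windowSize = 15000L, maskThreshold = 30L) {
    p <- computeRFD(counts, windowSize = windowSize,
                    maskThreshold = maskThreshold)
    segmentsFromStates(hmmDecode(quantileEncode(deltaRFD(p))), p,
                       counts = counts)
}
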