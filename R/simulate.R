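#' Configure a stochastic replication simulation
#'
#' Defines the replication program used by \code{\link{simulateReplication}}:
#' broad initiation zones that each support at most one initiation per cell
#' cycle at a uniformly random position within the zone, plus dispersed
#' background origins firing as an inhomogeneous Poisson process whose rate
#' grows exponentially through S phase (a cascade of late firing between
#' zones), with constant bidirectional fork speed.
#'
#' @param genomeLength Genome length in bp (single chromosome "chrSim").
#' @param binSize Bin width in bp (default 1000); \code{genomeLength} and all
#'   zone coordinates must be multiples of it.
#' @param zones data.frame with columns \code{start}, \code{end} (0-based
#'   half-open bp), \code{firingProbability} (fraction of cell cycles in which
#'   the zone fires), \code{timeMean}, \code{timeSd} (minutes; firing time is
#'   normal truncated at 0). See \code{\link{makeZones}}.
#' @param backgroundRate0 Background initiation rate at S-phase start,
#'   initiations per kb per minute (on unreplicated DNA only).
#' @param backgroundGrowth Per-minute multiplicative growth of the background
#'   rate (rate(t) = backgroundRate0 * exp(backgroundGrowth * t)).
#' @param forkSpeed Fork speed v in kb per minute.
#' @param nCells Number of simulated cells.
#' @param readDepth Expected sequenced reads per replicated kb (per
#'   replicate) when sampling OK-seq reads.
#' @param nReplicates Number of biological replicates to sample.
#' @param seed Integer seed; replicate r of the read sampling uses seed + r.
#' @return A validated list of class \code{simulationConfig}.
#' @examples
#' cfg <- simulationConfig(2e6, zones = makeZones(2e6, 4), nCells = 50)
#' @export
simulationConfig <- function(genomeLength, binSize = 1000L, zones,
                             backgroundRate0 = 1e-5, backgroundGrowth = 0.01,
                             forkSpeed = 1.5, nCells = 500L, readDepth = 50,
                             nReplicates = 2L, seed = 1L) {
    binSize <- as.integer(binSize)
    if (genomeLength %% binSize != 0)
        stop("genomeLength must be a multiple of binSize")
    zones <- as.data.frame(zones)
    need <- c("start", "end", "firingProbability", "timeMean", "timeSd")
    if (!all(need %in% names(zones)))
        stop("zones must have columns ", paste(need, collapse = ", "))
    if (nrow(zones) > 0) {
        zones <- zones[order(zones$start), , drop = FALSE]
        if (any(zones$end <= zones$start))
            stop("zones must have end > start")
        if (nrow(zones) > 1 &&
            any(zones$start[-1L] < zones$end[-nrow(zones)]))
            stop("zones must be non-overlapping")
        if (any(zones$firingProbability < 0 | zones$firingProbability > 1))
            stop("firingProbability must lie in [0,1]")
        if (any(zones$end > genomeLength))
            stop("zones must lie within the genome")
    }
    if (forkSpeed <= 0) stop("forkSpeed must be > 0")
    if (backgroundRate0 < 0) stop("backgroundRate0 must be >= 0")
    if (readDepth <= 0) stop("readDepth must be > 0")
    structure(list(genomeLength = as.numeric(genomeLength), binSize = binSize,
                   zones = zones, backgroundRate0 = backgroundRate0,
                   backgroundGrowth = backgroundGrowth, forkSpeed = forkSpeed,
                   nCells = as.integer(nCells), readDepth = readDepth,
                   nReplicates = as.integer(nReplicates),
                   seed = as.integer(seed)),
              class = "simulationConfig")
}

#' Evenly spaced initiation zones
#'
#' @param genomeLength Genome length (bp).
#' @param nZones Number of zones, centred at regular intervals.
#' @param width Zone width (bp, default 30000 -- the typical initiation-zone
#'   size observed by OK-seq).
#' @param firingProbability Scalar or per-zone vector of zone efficiencies.
#' @param timeMean,timeSd Firing-time distribution (minutes).
#' @return A zones data.frame for \code{\link{simulationConfig}}.
#' @export
makeZones <- function(genomeLength, nZones, width = 30000,
                      firingProbability = 0.6, timeMean = 60, timeSd = 30) {
    centers <- genomeLength * (seq_len(nZones) - 0.5) / nZones
    start <- round(centers - width / 2)
    data.frame(start = start, end = start + width,
               firingProbability = rep_len(firingProbability, nZones),
               timeMean = rep_len(timeMean, nZones),
               timeSd = rep_len(timeSd, nZones))
}

## Firing time of a zone: normal truncated at zero (resampled).
.truncNorm <- function(n, mean, sd) {
    if (n == 0L) return(numeric(0))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
}

## Lower envelope of t_i + |x - x_i|/v at bin centers; returns replication
## time T and winning origin index per bin. Background candidates are drawn
## on the whole genome and thinned by passive replication, which is
## equivalent to drawing on unreplicated DNA only. The envelope over ALL
## candidates equals the envelope over realized events only: a candidate
## whose position is passively replicated before it fires can never win
## anywhere (Lipschitz bound).
.envelopeBins <- function(pos, time, xc, vbp) {
    T <- rep(Inf, length(xc)); winner <- integer(length(xc))
    for (i in seq_along(pos)) {
        ti <- time[i] + abs(xc - pos[i]) / vbp
        upd <- ti < T
        if (any(upd)) { T[upd] <- ti[upd]; winner[upd] <- i }
    }
    list(T = T, winner = winner)
}

## Realized events: processed in firing order, an event is realized unless
## its position was already passively replicated by an earlier realized event.
.acceptEvents <- function(pos, time, vbp) {
    o <- order(time)
    accepted <- logical(length(pos))
    accPos <- accTime <- numeric(0)
    for (i in o) {
        if (length(accPos) == 0L ||
            time[i] < min(accTime + abs(pos[i] - accPos) / vbp)) {
            accepted[i] <- TRUE
            accPos <- c(accPos, pos[i]); accTime <- c(accTime, time[i])
        }
    }
    accepted
}

#' Simulate the replication of a cell population
#'
#' Draws, for each cell, zone firing events (at most one per zone per cell,
#' uniform position, truncated-normal time) and background initiations
#' (space-time Poisson process with exponentially growing rate, restricted to
#' unreplicated DNA by thinning), then propagates forks at constant speed in
#' both directions until converging forks meet. Cells in which no initiation
#' occurs are rejected and resampled (counted in \code{nResampled}).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \linkS4class{ReplicationTruth} with per-bin true RFD and MRT,
#'   per-cell realized initiation events, per-zone firing statistics and the
#'   total S-phase duration.
#' @examples
#' cfg <- simulationConfig(1e6, zones = makeZones(1e6, 1, firingProbability = 1),
#'                         backgroundRate0 = 0, nCells = 20, seed = 7)
#' truth <- simulateReplication(cfg)
#' range(trueRFD(truth))
#' @export
simulateReplication <- function(config) {
    stopifnot(inherits(config, "simulationConfig"))
    set.seed(config$seed)
    L <- config$genomeLength; bs <- config$binSize
    nBins <- as.integer(L / bs)
    xc <- (seq_len(nBins) - 0.5) * bs
    vbp <- config$forkSpeed * 1000
    sumT <- numeric(nBins); rightCount <- integer(nBins)
    events <- vector("list", config$nCells)
    nRes <- 0L; tS <- 0
    nz <- nrow(config$zones)
    zoneScheduled <- integer(nz); zoneRealized <- integer(nz)
    for (cell in seq_len(config$nCells)) {
        cellDraw <- NULL; tries <- 0L
        while (is.null(cellDraw)) {
            tries <- tries + 1L
            if (tries > 100L)
                stop("zero initiation events in 100 consecutive draws; ",
                     "check firing probabilities and backgroundRate0")
            d <- .drawCell(config, xc, vbp)
            if (is.null(d)) nRes <- nRes + 1L else cellDraw <- d
        }
        if (tries > 1L)
            message("cell ", cell, ": resampled ", tries - 1L,
                    " draw(s) with no initiation")
        T <- cellDraw$env$T; winner <- cellDraw$env$winner
        sumT <- sumT + T
        rightCount <- rightCount + as.integer(xc > cellDraw$pos[winner])
        tS <- max(tS, max(T))
        acc <- .acceptEvents(cellDraw$pos, cellDraw$time, vbp)
        zi <- grep("^zone", cellDraw$src)
        if (length(zi)) {
            idx <- as.integer(sub("zone", "", cellDraw$src[zi]))
            zoneScheduled[idx] <- zoneScheduled[idx] + 1L
            ridx <- idx[acc[zi]]
            zoneRealized[ridx] <- zoneRealized[ridx] + 1L
        }
        events[[cell]] <- data.frame(position = cellDraw$pos[acc],
                                     time = cellDraw$time[acc],
                                     source = cellDraw$src[acc])
    }
    bins <- GRanges("chrSim", IRanges(start = seq(1L, by = bs,
                                                  length.out = nBins),
                                      width = bs))
    zs <- cbind(config$zones,
                data.frame(nScheduled = zoneScheduled,
                           nRealized = zoneRealized,
                           realizedEfficiency = zoneRealized / config$nCells))
    new("ReplicationTruth", config = unclass(config), bins = bins,
        rfd = (2 * rightCount - config$nCells) / config$nCells,
        mrt = sumT / config$nCells, rightCount = rightCount,
        events = events, zoneStats = zs, tS = tS,
        nCells = config$nCells, nResampled = nRes)
}

## .drawCell with the envelope evaluated on provided bin centers.
.drawCell <- function(cfg, xc, vbp) {
    z <- cfg$zones
    fires <- if (nrow(z)) stats::runif(nrow(z)) < z$firingProbability
             else logical(0)
    pos <- time <- numeric(0); src <- character(0)
    if (any(fires)) {
        zi <- which(fires)
        pos <- stats::runif(length(zi), z$start[zi], z$end[zi])
        time <- .truncNorm(length(zi), z$timeMean[zi], z$timeSd[zi])
        src <- paste0("zone", zi)
    }
    g <- cfg$backgroundGrowth; r0 <- cfg$backgroundRate0
    Lkb <- cfg$genomeLength / 1000
    tLo <- 0
    tHi <- max(30, if (length(time)) max(time) else 0)
    repeat {
        if (r0 > 0) {
            lam <- if (abs(g) < 1e-12) r0 * Lkb * (tHi - tLo)
                   else r0 * Lkb * (exp(g * tHi) - exp(g * tLo)) / g
            if (lam > 1e6)
                stop("background origin rate diverges; lower backgroundGrowth")
            nb <- stats::rpois(1L, lam)
            if (nb > 0) {
                u <- stats::runif(nb)
                tb <- if (abs(g) < 1e-12) tLo + u * (tHi - tLo)
                      else log(exp(g * tLo) + u * (exp(g * tHi) -
                                                   exp(g * tLo))) / g
                pos <- c(pos, stats::runif(nb, 0, cfg$genomeLength))
                time <- c(time, tb)
                src <- c(src, rep("background", nb))
            }
        }
        if (length(pos) == 0L) {
            if (r0 == 0) return(NULL)
            tLo <- tHi; tHi <- tHi * 2
            next
        }
        env <- .envelopeBins(pos, time, xc, vbp)
        if (max(env$T) <= tHi || r0 == 0)
            return(list(pos = pos, time = time, src = src, env = env))
        tLo <- tHi; tHi <- tHi * 2
    }
}

#' Sample strand-resolved OK-seq read counts from a simulation
#'
#' For each replicate independently, per-bin Crick counts are
#' Poisson(depth x fraction of cells replicating the bin rightward) and
#' Watson counts Poisson(depth x fraction leftward): rightward-moving forks
#' synthesize Okazaki fragments on the Crick strand, leftward-moving forks on
#' the Watson strand.
#'
#' @param truth A \linkS4class{ReplicationTruth}.
#' @param config Optional \code{\link{simulationConfig}} overriding the one
#'   stored in \code{truth} (e.g. to change \code{readDepth}).
#' @return A list of \linkS4class{StrandedBinCounts}, one per replicate.
#' @export
sampleOkSeqReads <- function(truth, config = NULL) {
    cfg <- if (is.null(config)) truth@config else unclass(config)
    if (cfg$readDepth <= 0) stop("readDepth must be > 0")
    nBins <- length(truth@bins)
    fracRight <- truth@rightCount / truth@nCells
    mu <- cfg$readDepth * cfg$binSize / 1000
    starts <- start(truth@bins) - 1L
    lapply(seq_len(cfg$nReplicates), function(r) {
        set.seed(cfg$seed + r)
        C <- stats::rpois(nBins, mu * fracRight)
        W <- stats::rpois(nBins, mu * (1 - fracRight))
        StrandedBinCounts(rep("chrSim", nBins), starts, W = W, C = C,
                          binSize = cfg$binSize)
    })
}

#' Simulate a six-fraction Repli-seq profile
#'
#' Splits S phase [0, tS] into six equal compartments and reports, per bin,
#' the fraction of cells whose replication time of that bin falls in each
#' compartment (enrichments sum to 1 per bin).
#'
#' @param truth A \linkS4class{ReplicationTruth}.
#' @return A \linkS4class{TimingProfile}.
#' @export
simulateRepliSeq <- function(truth) {
    cfg <- truth@config
    nBins <- length(truth@bins)
    xc <- (seq_len(nBins) - 0.5) * cfg$binSize
    vbp <- cfg$forkSpeed * 1000
    counts <- matrix(0L, nBins, 6L)
    for (ev in truth@events) {
        T <- .envelopeBins(ev$position, ev$time, xc, vbp)$T
        comp <- pmin(6L, pmax(1L, ceiling(T / truth@tS * 6)))
        for (k in 1:6) counts[, k] <- counts[, k] + (comp == k)
    }
    new("TimingProfile", bins = truth@bins,
        enrichment = counts / truth@nCells,
        s50 = rep(NA_real_, nBins))
}

#' Reconstruct the fork-direction track of a single simulated cell
#'
#' @param truth A \linkS4class{ReplicationTruth}.
#' @param cell Cell index.
#' @return Character vector per bin, "rightward" or "leftward".
#' @export
cellForkDirections <- function(truth, cell) {
    cfg <- truth@config
    ev <- truth@events[[cell]]
    xc <- (seq_len(length(truth@bins)) - 0.5) * cfg$binSize
    env <- .envelopeBins(ev$position, ev$time, xc, cfg$forkSpeed * 1000)
    ifelse(xc > ev$position[env$winner], "rightward", "leftward")
}

#' Generate a synthetic gene annotation around initiation zones
#'
#' Places active (and optionally inactive) genes at controlled positions and
#' orientations relative to initiation zones, recording the construction as
#' truth labels, so that downstream gene-context classification can be tested
#' against a known answer.
#'
#' @param config A \code{\link{simulationConfig}} (provides genome length).
#' @param zones Zones data.frame (as in the config).
#' @param placements Character per zone: \code{"both"} (active genes on both
#'   sides, expected type 1), \code{"left"}/\code{"right"} (one active gene,
#'   expected type 2), \code{"none"} (no gene within the flank, expected
#'   type 3), \code{"inactive-both"} (flanking genes with zero expression,
#'   expected type 3). Recycled.
#' @param orientations For two-sided placements: \code{"divergent"}
#'   (genes transcribe away from the zone), \code{"tandem"} (both rightward)
#'   or \code{"convergent"}. Recycled.
#' @param geneLength Gene length in bp.
#' @param gap Distance between zone border and the nearest gene end (bp);
#'   keep below the typing flank (20 kb) for flanked placements.
#' @param expression FPKM-like expression assigned to active genes.
#' @return A \link[GenomicRanges]{GRanges} of genes with metadata columns
#'   \code{name}, \code{expression}, \code{active}, \code{zone},
#'   \code{placement}, \code{expectedType}.
#' @export
generateGeneAnnotation <- function(config, zones,
                                   placements = c("both", "left", "none"),
                                   orientations = "divergent",
                                   geneLength = 20000, gap = 10000,
                                   expression = 10) {
    zones <- as.data.frame(zones)
    nz <- nrow(zones)
    placements <- rep_len(placements, nz)
    orientations <- rep_len(orientations, nz)
    L <- config$genomeLength
    res <- list()
    for (i in seq_len(nz)) {
        pl <- placements[i]
        if (pl == "none") next
        expr <- if (pl == "inactive-both") 0 else expression
        side <- switch(pl, both = , `inactive-both` = c("L", "R"),
                       left = "L", right = "R")
        ori <- orientations[i]
        for (s in side) {
            if (s == "L") {
                gStart <- zones$start[i] - gap - geneLength
                gEnd <- zones$start[i] - gap
                strand <- switch(ori, divergent = "-", tandem = "+",
                                 convergent = "+")
            } else {
                gStart <- zones$end[i] + gap
                gEnd <- gStart + geneLength
                strand <- switch(ori, divergent = "+", tandem = "+",
                                 convergent = "-")
            }
            if (gStart < 0 || gEnd > L)
                stop("requested gene does not fit in the genome at zone ", i)
            res[[length(res) + 1L]] <- data.frame(
                start = gStart, end = gEnd, strand = strand,
                expression = expr, zone = i, placement = pl)
        }
    }
    expected <- ifelse(placements %in% c("both"), 1L,
                ifelse(placements %in% c("left", "right"), 2L, 3L))
    if (length(res) == 0L) {
        gr <- GRanges()
    } else {
        d <- do.call(rbind, res)
        if (nrow(d) > 1L) {
            o <- order(d$start)
            if (any(d$start[o][-1L] < d$end[o][-nrow(d)]))
                stop("requested genes overlap; reduce geneLength or gap")
        }
        gr <- GRanges("chrSim", IRanges(start = d$start + 1L, end = d$end),
                      strand = d$strand,
                      name = paste0("gene", seq_len(nrow(d))),
                      expression = d$expression,
                      active = d$expression > 0,
                      zone = d$zone, placement = d$placement)
        gr <- sort(gr, ignore.strand = TRUE)
    }
    metadata(gr)$expectedType <- expected
    gr
}
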