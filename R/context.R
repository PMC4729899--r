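## Utilities ------------------------------------------------------------

.activeGenes <- function(genes, activeThreshold = 0) {
    if (!"expression" %in% colnames(mcols(genes)))
        stop("genes must carry an 'expression' metadata column")
    genes[mcols(genes)$expression > activeThreshold]
}

.asRanges <- function(x, state = NULL) {
    gr <- if (is(x, "SegmentSet")) x@segments else x
    if (!is.null(state) && "state" %in% colnames(mcols(gr)))
        gr <- gr[mcols(gr)$state == state]
    gr
}

#' Remove genes nested in a same-strand gene
#'
#' Genes entirely included within another gene in the same orientation are
#' dropped before any gene-context analysis.
#'
#' @param genes A \link[GenomicRanges]{GRanges} of genes with strand.
#' @return The filtered \link[GenomicRanges]{GRanges}.
#' @export
cleanGeneAnnotation <- function(genes) {
    if (length(genes) < 2L) return(genes)
    h <- findOverlaps(genes, genes, type = "within", ignore.strand = TRUE)
    q <- S4Vectors::queryHits(h); su <- S4Vectors::subjectHits(h)
    sameStrand <- as.character(strand(genes))[q] ==
        as.character(strand(genes))[su]
    nested <- q != su & sameStrand &
        (width(genes)[q] < width(genes)[su] |
         (width(genes)[q] == width(genes)[su] & q > su))
    if (any(nested)) genes[-unique(q[nested])] else genes
}

## Non-transcribed intervals bounded by active genes on both sides.
.boundedIntergaps <- function(active) {
    red <- reduce(active, ignore.strand = TRUE)
    out <- list()
    for (ch in unique(as.character(seqnames(red)))) {
        g <- red[seqnames(red) == ch]
        if (length(g) < 2L) next
        o <- order(start(g)); g <- g[o]
        s <- end(g)[-length(g)] + 1L
        e <- start(g)[-1L] - 1L
        keep <- e >= s
        if (any(keep)) out[[length(out) + 1L]] <-
            GRanges(ch, IRanges(start = s[keep], end = e[keep]))
    }
    if (length(out) == 0L) return(GRanges())
    unname(do.call(c, out))
}

## AS typing ------------------------------------------------------------

#' Classify initiation zones by their gene context
#'
#' Type 1: the zone is flanked by active genes (at least two within
#' \code{flank}) and more than half of it lies within a non-transcribed
#' interval bounded by active genes on both sides. Otherwise type 2 if
#' exactly one active gene lies within \code{flank} of the zone, type 3 if
#' none does, and type 4 for the remainder (several flanking active genes
#' without the bounded-intergap geometry). Typing is exhaustive and
#' exclusive.
#'
#' @param as A \linkS4class{SegmentSet} (its AS are used) or a
#'   \link[GenomicRanges]{GRanges} of ascending segments.
#' @param genes Gene \link[GenomicRanges]{GRanges} with \code{expression}.
#' @param flank Flank distance in bp (default 20000).
#' @param activeThreshold Expression above which a gene counts as active.
#' @return Integer vector of types (1..4), one per ascending segment.
#' @export
classifyASTypes <- function(as, genes, flank = 20000L, activeThreshold = 0) {
    asr <- .asRanges(as, "AS")
    genes <- cleanGeneAnnotation(genes)
    active <- .activeGenes(genes, activeThreshold)
    n <- length(asr)
    if (n == 0L) return(integer(0))
    gaps <- .boundedIntergaps(active)
    inGap <- rep(FALSE, n)
    if (length(gaps)) {
        h <- findOverlaps(asr, gaps)
        if (length(h)) {
            ov <- width(pintersect(asr[S4Vectors::queryHits(h)],
                                   gaps[S4Vectors::subjectHits(h)]))
            frac <- ov / width(asr)[S4Vectors::queryHits(h)]
            best <- tapply(frac, S4Vectors::queryHits(h), max)
            inGap[as.integer(names(best))] <- best > 0.5
        }
    }
    ext <- asr
    start(ext) <- pmax(1L, start(ext) - flank)
    end(ext) <- end(ext) + flank
    nAct <- countOverlaps(ext, active, ignore.strand = TRUE)
    ifelse(nAct >= 2L & inGap, 1L,
    ifelse(nAct == 1L, 2L,
    ifelse(nAct == 0L, 3L, 4L)))
}

## Distances ------------------------------------------------------------

## Signed distance from point p (0-based) to nearest extremity of `gr`;
## 0 if p lies inside any interval of gr.
.distToExtremities <- function(p, chrom, gr) {
    if (length(gr) == 0L) return(NA_real_)
    g <- gr[as.character(seqnames(gr)) == chrom]
    if (length(g) == 0L) return(NA_real_)
    if (any(p >= start(g) - 1L & p < end(g))) return(0)
    ext <- c(start(g) - 1L, end(g))
    d <- ext - p
    d[which.min(abs(d))]
}

#' Distances from initiation-zone ends to the nearest gene extremities
#'
#' For each ascending-segment extremity, the signed distance (bp; positive
#' when the gene extremity lies to the right) to the closest extremity of an
#' active and of an inactive gene; zero when the zone end falls inside a
#' gene of that class.
#'
#' @inheritParams classifyASTypes
#' @return data.frame with columns \code{as} (index), \code{side}
#'   ("left"/"right"), \code{class} ("active"/"inactive"),
#'   \code{distance} (\code{NA} when the chromosome has no gene of the
#'   class).
#' @export
nearestGeneDistances <- function(as, genes, activeThreshold = 0) {
    asr <- .asRanges(as, "AS")
    genes <- cleanGeneAnnotation(genes)
    active <- .activeGenes(genes, activeThreshold)
    inactive <- genes[mcols(genes)$expression <= activeThreshold]
    rows <- list()
    for (i in seq_along(asr)) {
        ch <- as.character(seqnames(asr)[i])
        for (side in c("left", "right")) {
            p <- if (side == "left") start(asr)[i] - 1L else end(asr)[i]
            for (cl in c("active", "inactive")) {
                gr <- if (cl == "active") active else inactive
                rows[[length(rows) + 1L]] <- data.frame(
                    as = i, side = side, class = cl,
                    distance = .distToExtremities(p, ch, gr))
            }
        }
    }
    do.call(rbind, rows)
}

## Shuffle null ----------------------------------------------------------

#' Shuffle alternating segments and gaps along a virtual chromosome
#'
#' Permutes the segment lengths and, independently, the internal gap
#' lengths, preserving the alternation segment/gap and the leading and
#' trailing gaps; the number and length multiset of segments (and of
#' internal gaps) are conserved exactly.
#'
#' @param starts,ends 0-based half-open segment coordinates on the virtual
#'   chromosome (sorted, non-overlapping).
#' @param chromLength Virtual chromosome length.
#' @return data.frame with shuffled \code{start}, \code{end}.
#' @export
shuffleSegments <- function(starts, ends, chromLength) {
    k <- length(starts)
    stopifnot(length(ends) == k, k >= 1L)
    lens <- ends - starts
    lead <- starts[1L]
    gapsInt <- if (k > 1L) starts[-1L] - ends[-k] else numeric(0)
    lens <- sample(lens)
    if (length(gapsInt) > 1L) gapsInt <- sample(gapsInt)
    newStarts <- numeric(k); newEnds <- numeric(k)
    pos <- lead
    for (i in seq_len(k)) {
        newStarts[i] <- pos
        newEnds[i] <- pos + lens[i]
        pos <- newEnds[i] + if (i < k) gapsInt[i] else 0
    }
    stopifnot(max(newEnds) <= chromLength + 1e-9)
    data.frame(start = newStarts, end = newEnds)
}

## Map 0-based points within regions to the concatenated virtual coordinate.
.toVirtual <- function(points, regions) {
    offs <- c(0, cumsum(width(regions)))[seq_along(regions)]
    idx <- findInterval(points, start(regions) - 1L)
    ok <- idx >= 1L & points < end(regions)[pmax(idx, 1L)]
    v <- rep(NA_real_, length(points))
    v[ok] <- offs[idx[ok]] + (points[ok] - (start(regions)[idx[ok]] - 1L))
    v
}

#' Timing-stratified shuffle null for zone-to-gene distances
#'
#' Regions of the genome sharing a replication-timing class are concatenated
#' into one virtual chromosome per class; on each, the ascending segments
#' and the gaps separating them are shuffled (alternation preserved, length
#' multisets conserved), and the distances from shuffled zone extremities to
#' the nearest active/inactive gene extremities are recomputed. The mean
#' over \code{nSims} shuffles (default 1000) is the neutral expectation.
#'
#' @param as \linkS4class{SegmentSet} or GRanges of ascending segments with
#'   a \code{timingClass} metadata column.
#' @param timingRegions \link[GenomicRanges]{GRanges} tiling the analysed
#'   genome with a \code{timingClass} metadata column.
#' @param genes Gene annotation with \code{expression}.
#' @param nSims Number of shuffles.
#' @param seed Optional integer seed.
#' @param breaks Distance histogram breaks (bp, on |distance|).
#' @param activeThreshold Expression activity cutoff.
#' @return A list: \code{breaks}; data.frames \code{observed} and
#'   \code{null} (columns \code{class}, \code{bin}, \code{count} resp.
#'   \code{mean}, \code{lo}, \code{hi} = 2.5/97.5 percentiles);
#'   \code{flaggedClasses}, timing classes with fewer than two zones
#'   (passed through unshuffled).
#' @export
shuffleNull <- function(as, timingRegions, genes, nSims = 1000L,
                        seed = NULL, breaks = c(seq(0, 1e5, 5e3), Inf),
                        activeThreshold = 0) {
    if (!is.null(seed)) set.seed(seed)
    asr <- .asRanges(as, "AS")
    if (!"timingClass" %in% colnames(mcols(asr)) ||
        anyNA(mcols(asr)$timingClass))
        stop("every ascending segment needs a timingClass")
    genes <- cleanGeneAnnotation(genes)
    active <- .activeGenes(genes, activeThreshold)
    inactive <- genes[mcols(genes)$expression <= activeThreshold]
    classes <- unique(mcols(asr)$timingClass)
    flagged <- character(0)
    nb <- length(breaks) - 1L
    obsA <- obsI <- numeric(nb)
    simA <- matrix(0, nSims, nb); simI <- matrix(0, nSims, nb)
    histCount <- function(d) {
        d <- abs(d[!is.na(d)])
        if (length(d) == 0L) return(numeric(nb))
        as.numeric(table(cut(d, breaks, include.lowest = TRUE)))
    }
    extremities <- function(gr) sort(c(start(gr) - 1L, end(gr)))
    distsTo <- function(p, ext, iv) {
        if (length(ext) == 0L) return(rep(NA_real_, length(p)))
        vapply(p, function(pp) {
            if (length(iv) && any(pp >= iv$s & pp < iv$e)) return(0)
            d <- ext - pp
            d[which.min(abs(d))]
        }, 0)
    }
    for (cl in classes) {
        reg <- timingRegions[mcols(timingRegions)$timingClass == cl]
        reg <- sort(reg)
        if (length(reg) == 0L) stop("no timing region for class ", cl)
        zsel <- asr[mcols(asr)$timingClass == cl]
        vs <- .toVirtual(start(zsel) - 1L, reg)
        ve <- .toVirtual(end(zsel) - 1L, reg) + 1L
        ok <- !is.na(vs) & !is.na(ve)
        vs <- vs[ok]; ve <- ve[ok]
        o <- order(vs); vs <- vs[o]; ve <- ve[o]
        vlen <- sum(width(reg))
        extA <- .toVirtual(extremities(active), reg)
        extA <- sort(extA[!is.na(extA)])
        extI <- .toVirtual(extremities(inactive), reg)
        extI <- sort(extI[!is.na(extI)])
        ivA <- {
            gs <- .toVirtual(start(active) - 1L, reg)
            ge <- .toVirtual(end(active) - 1L, reg) + 1L
            k <- !is.na(gs) & !is.na(ge)
            list(s = gs[k], e = ge[k])
        }
        ivI <- {
            gs <- .toVirtual(start(inactive) - 1L, reg)
            ge <- .toVirtual(end(inactive) - 1L, reg) + 1L
            k <- !is.na(gs) & !is.na(ge)
            list(s = gs[k], e = ge[k])
        }
        pObs <- c(vs, ve)
        obsA <- obsA + histCount(distsTo(pObs, extA, ivA))
        obsI <- obsI + histCount(distsTo(pObs, extI, ivI))
        if (length(vs) < 2L) {
            flagged <- c(flagged, cl)
            for (s in seq_len(nSims)) {
                simA[s, ] <- simA[s, ] + histCount(distsTo(pObs, extA, ivA))
                simI[s, ] <- simI[s, ] + histCount(distsTo(pObs, extI, ivI))
            }
            next
        }
        for (s in seq_len(nSims)) {
            sh <- shuffleSegments(vs, ve, vlen)
            stopifnot(identical(sort(sh$end - sh$start), sort(ve - vs)))
            p <- c(sh$start, sh$end)
            simA[s, ] <- simA[s, ] + histCount(distsTo(p, extA, ivA))
            simI[s, ] <- simI[s, ] + histCount(distsTo(p, extI, ivI))
        }
    }
    mids <- breaks[-length(breaks)]
    list(breaks = breaks,
         observed = data.frame(class = rep(c("active", "inactive"),
                                           each = nb),
                               bin = rep(mids, 2L),
                               count = c(obsA, obsI)),
         null = data.frame(class = rep(c("active", "inactive"), each = nb),
                           bin = rep(mids, 2L),
                           mean = c(colMeans(simA), colMeans(simI)),
                           lo = c(apply(simA, 2L, stats::quantile, 0.025),
                                  apply(simI, 2L, stats::quantile, 0.025)),
                           hi = c(apply(simA, 2L, stats::quantile, 0.975),
                                  apply(simI, 2L, stats::quantile, 0.975))),
         flaggedClasses = flagged, nSims = nSims)
}

## Intergene / orientation analyses --------------------------------------

#' Initiation between active genes by intergap size and orientation
#'
#' Each interval between consecutive active genes is classified divergent
#' (flanking genes transcribe away from the gap), tandem or convergent, and
#' counted as initiation-positive when it overlaps an ascending segment by
#' at least one nucleotide.
#'
#' @inheritParams classifyASTypes
#' @param sizeBreaks Intergap size bins (bp).
#' @return data.frame with \code{orientation}, \code{sizeBin}, \code{n} and
#'   \code{proportion} of intergaps overlapping an AS.
#' @export
intergeneInitiation <- function(as, genes,
                                sizeBreaks = c(0, 2e4, 5e4, 1e5, Inf),
                                activeThreshold = 0) {
    asr <- .asRanges(as, "AS")
    active <- .activeGenes(cleanGeneAnnotation(genes), activeThreshold)
    rows <- list()
    for (ch in unique(as.character(seqnames(active)))) {
        g <- active[seqnames(active) == ch]
        if (length(g) < 2L) next
        o <- order(start(g)); g <- g[o]
        s <- end(g)[-length(g)] + 1L
        e <- start(g)[-1L] - 1L
        sl <- as.character(strand(g))[-length(g)]
        sr <- as.character(strand(g))[-1L]
        keep <- e >= s
        if (!any(keep)) next
        ori <- ifelse(sl == "-" & sr == "+", "divergent",
               ifelse(sl == "+" & sr == "-", "convergent", "tandem"))
        gap <- GRanges(ch, IRanges(start = s[keep], end = e[keep]))
        rows[[length(rows) + 1L]] <- data.frame(
            width = width(gap), orientation = ori[keep],
            hit = countOverlaps(gap, asr, ignore.strand = TRUE) > 0L)
    }
    if (length(rows) == 0L)
        return(data.frame(orientation = character(0), sizeBin = character(0),
                          n = integer(0), proportion = numeric(0)))
    d <- do.call(rbind, rows)
    d$sizeBin <- cut(d$width, sizeBreaks, include.lowest = TRUE)
    agg <- stats::aggregate(hit ~ orientation + sizeBin, data = d,
                            FUN = function(x) c(n = length(x),
                                                p = mean(x)))
    data.frame(orientation = agg$orientation, sizeBin = agg$sizeBin,
               n = agg$hit[, "n"], proportion = agg$hit[, "p"])
}

#' RFD grouped by gene orientation and activity
#'
#' Each unmasked RFD window is assigned to the feature containing its
#' center: active gene transcribed rightward (+ strand), active gene
#' transcribed leftward, inactive gene, or intergene; windows covered by
#' genes on both strands are excluded and counted. Co-orientation of
#' replication with transcription appears as a positive mean RFD in
#' rightward genes and a negative one in leftward genes.
#'
#' @param profile An \linkS4class{RFDProfile}.
#' @inheritParams classifyASTypes
#' @param histBreaks Histogram breaks on RFD.
#' @return A list with \code{groups} (per-window factor), \code{means}
#'   (named mean RFD per group), \code{histograms} (matrix bins x groups)
#'   and \code{nExcluded}.
#' @export
rfdTranscriptionCoorientation <- function(profile, genes,
                                          activeThreshold = 0,
                                          histBreaks = seq(-1, 1, 0.1)) {
    genes <- cleanGeneAnnotation(genes)
    w <- profile@windows
    ok <- !mcols(w)$masked
    centers <- GRanges(seqnames(w), IRanges(start = start(w) +
                                            width(w) %/% 2L, width = 1L))
    act <- mcols(genes)$expression > activeThreshold
    grp <- rep("intergene", length(w))
    hasPlus <- countOverlaps(centers, genes[as.character(strand(genes)) ==
                                            "+"], ignore.strand = TRUE) > 0L
    hasMinus <- countOverlaps(centers, genes[as.character(strand(genes)) ==
                                             "-"], ignore.strand = TRUE) > 0L
    excl <- hasPlus & hasMinus
    inAct <- countOverlaps(centers, genes[act], ignore.strand = TRUE) > 0L
    inActPlus <- countOverlaps(centers,
        genes[act & as.character(strand(genes)) == "+"],
        ignore.strand = TRUE) > 0L
    inActMinus <- countOverlaps(centers,
        genes[act & as.character(strand(genes)) == "-"],
        ignore.strand = TRUE) > 0L
    inAny <- hasPlus | hasMinus
    grp[inAny & !inAct] <- "inactive"
    grp[inActPlus] <- "rightward"
    grp[inActMinus] <- "leftward"
    grp[excl] <- NA_character_
    grp[!ok] <- NA_character_
    groups <- factor(grp, levels = c("rightward", "leftward", "inactive",
                                     "intergene"))
    vals <- mcols(w)$rfd
    means <- tapply(vals, groups, mean, na.rm = TRUE)
    hists <- vapply(levels(groups), function(l) {
        v <- vals[!is.na(groups) & groups == l]
        v <- v[!is.na(v)]
        if (length(v) == 0L) return(numeric(length(histBreaks) - 1L))
        as.numeric(table(cut(v, histBreaks, include.lowest = TRUE)))
    }, numeric(length(histBreaks) - 1L))
    list(groups = groups, means = means, histograms = hists,
         nExcluded = sum(excl & ok, na.rm = TRUE))
}

#' High-|RFD| flat segments and their relation to co-oriented genes
#'
#' Flat segments with mean |RFD| above 0.6 replicate almost exclusively in
#' one direction. For each, this reports the replication direction, the
#' distances from both ends to the nearest co-oriented and counter-oriented
#' active gene extremity, and the fraction of the segment covered by
#' co-oriented active genes, counter-oriented active genes, inactive genes
#' and intergenic sequence.
#'
#' @param segset A \linkS4class{SegmentSet} (FS with \code{meanAbsRFD}).
#' @param profile The \linkS4class{RFDProfile} (used for the signed mean
#'   RFD of each flat segment).
#' @inheritParams classifyASTypes
#' @return data.frame, one row per flagged FS: coordinates, \code{meanRFD},
#'   \code{direction}, signed end distances \code{dCoLeft}, \code{dCoRight},
#'   \code{dCounterLeft}, \code{dCounterRight} and coverage fractions
#'   \code{covCo}, \code{covCounter}, \code{covInactive}, \code{covIntergene}.
#' @export
highRfdFsStats <- function(segset, profile, genes, activeThreshold = 0) {
    genes <- cleanGeneAnnotation(genes)
    fs <- .asRanges(segset, "FS")
    w <- profile@windows
    rows <- list()
    for (i in seq_along(fs)) {
        sel <- findOverlaps(fs[i], w)
        vals <- mcols(w)$rfd[S4Vectors::subjectHits(sel)]
        vals <- vals[!is.na(vals)]
        if (length(vals) == 0L) next
        mAbs <- mean(abs(vals))
        if (mAbs <= 0.6) next
        mRfd <- mean(vals)
        dir <- if (mRfd >= 0) "+" else "-"
        act <- .activeGenes(genes, activeThreshold)
        co <- act[as.character(strand(act)) == dir]
        counter <- act[as.character(strand(act)) != dir]
        inact <- genes[mcols(genes)$expression <= activeThreshold]
        ch <- as.character(seqnames(fs)[i])
        pL <- start(fs)[i] - 1L; pR <- end(fs)[i]
        covFrac <- function(gr) {
            if (length(gr) == 0L) return(0)
            ov <- intersect(reduce(gr, ignore.strand = TRUE), fs[i],
                            ignore.strand = TRUE)
            sum(width(ov)) / width(fs[i])
        }
        cc <- covFrac(co); cn <- covFrac(counter); ci <- covFrac(inact)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = pL, end = pR, meanRFD = mRfd,
            meanAbsRFD = mAbs, direction = dir,
            dCoLeft = .distToExtremities(pL, ch, co),
            dCoRight = .distToExtremities(pR, ch, co),
            dCounterLeft = .distToExtremities(pL, ch, counter),
            dCounterRight = .distToExtremities(pR, ch, counter),
            covCo = cc, covCounter = cn, covInactive = ci,
            covIntergene = max(0, 1 - cc - cn - ci))
    }
    if (length(rows) == 0L) return(data.frame())
    do.call(rbind, rows)
}

## Enrichment profiles ---------------------------------------------------

#' Feature density around (or along) anchor segments
#'
#' In absolute mode, feature midpoints are collected in bins of relative
#' position around every anchor border, oriented so that positive positions
#' point into the anchor; in rescaled mode, midpoints falling inside an
#' anchor are binned by their relative position 0..1 along it. Densities
#' are normalized by the average density within the examined region, so the
#' profile has mean 1 by construction.
#'
#' @param features \link[GenomicRanges]{GRanges} of features.
#' @param anchors \link[GenomicRanges]{GRanges} of anchor segments.
#' @param span Half-width (bp) of the examined region in absolute mode.
#' @param binWidth Bin width (bp) in absolute mode.
#' @param rescale Use rescaled mode.
#' @param nBins Number of bins in rescaled mode.
#' @return data.frame with \code{position} (bp relative to the border, or
#'   0..1) and \code{density} (1 = regional average). An empty feature set
#'   yields an all-zero profile with a warning.
#' @export
featureEnrichment <- function(features, anchors, span = 50000L,
                              binWidth = 1000L, rescale = FALSE,
                              nBins = 50L) {
    mids <- start(features) - 1L + width(features) / 2
    fch <- as.character(seqnames(features))
    if (rescale) {
        edges <- seq(0, 1, length.out = nBins + 1L)
        counts <- numeric(nBins)
        for (i in seq_along(anchors)) {
            sel <- fch == as.character(seqnames(anchors)[i]) &
                mids >= start(anchors)[i] - 1L & mids < end(anchors)[i]
            if (!any(sel)) next
            rel <- (mids[sel] - (start(anchors)[i] - 1L)) / width(anchors)[i]
            counts <- counts + tabulate(pmin(nBins,
                findInterval(rel, edges)), nBins)
        }
        pos <- (edges[-1L] + edges[-length(edges)]) / 2
    } else {
        edges <- seq(-span, span, by = binWidth)
        nb <- length(edges) - 1L
        counts <- numeric(nb)
        for (i in seq_along(anchors)) {
            ch <- as.character(seqnames(anchors)[i])
            sel <- fch == ch
            if (!any(sel)) next
            for (border in c("L", "R")) {
                rel <- if (border == "L") mids[sel] - (start(anchors)[i] - 1L)
                       else end(anchors)[i] - mids[sel]
                rel <- rel[rel >= -span & rel < span]
                if (length(rel))
                    counts <- counts + tabulate(findInterval(rel, edges), nb)
            }
        }
        pos <- (edges[-1L] + edges[-length(edges)]) / 2
    }
    if (sum(counts) == 0) {
        warning("no feature falls in the examined region; all-zero profile")
        return(data.frame(position = pos, density = counts))
    }
    data.frame(position = pos, density = counts / mean(counts))
}

#' Fraction of genomic bins overlapping an anchor, by distance from
#' reference points
#'
#' For each offset bin around every reference point, the fraction of
#' (point, offset) windows that overlap at least one anchor; this profiles
#' for example how initiation zones distribute around domain borders.
#'
#' @param anchors \link[GenomicRanges]{GRanges} (e.g. ascending segments).
#' @param referencePoints \link[GenomicRanges]{GRanges} of points.
#' @param span Maximum |offset| (bp).
#' @param binWidth Offset bin width (bp, default 100000).
#' @return data.frame with \code{offset} (bin center, bp) and
#'   \code{fraction}.
#' @export
overlapFractionProfile <- function(anchors, referencePoints, span = 1e6,
                                   binWidth = 1e5) {
    offs <- seq(-span, span - binWidth, by = binWidth)
    frac <- vapply(offs, function(o) {
        s <- start(referencePoints) + o
        probe <- GRanges(seqnames(referencePoints),
                         IRanges(start = pmax(1, s), width = binWidth))
        mean(countOverlaps(probe, anchors, ignore.strand = TRUE) > 0L)
    }, 0)
    data.frame(offset = offs + binWidth / 2, fraction = frac)
}

## Hi-C directionality ---------------------------------------------------

#' Hi-C directionality index
#'
#' For each bin with \code{A} contacts to the upstream and \code{B} to the
#' downstream flank, with expectation E = (A+B)/2 under no bias, the
#' directionality index is sign(B - A) x ((A-E)^2/E + (B-E)^2/E); it is 0
#' when A = B or when the bin has no contacts. Large positive values mark
#' downstream-biased bins (domain left borders), large negative values
#' upstream-biased bins.
#'
#' @param A,B Non-negative contact counts per bin (conventionally 40-kb
#'   bins against 2-Mb flanks).
#' @return Numeric DI per bin.
#' @examples
#' directionalityIndex(c(10, 0, 20), c(10, 20, 0))
#' @export
directionalityIndex <- function(A, B) {
    if (any(A < 0) || any(B < 0)) stop("contact counts must be non-negative")
    E <- (A + B) / 2
    di <- ifelse(E > 0, sign(B - A) * ((A - E)^2 + (B - E)^2) / E, 0)
    as.numeric(di)
}
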