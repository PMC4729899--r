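## RFD in a window of `window` bp centered at genomic point `pos` (0-based).
.rfdAtPoint <- function(dense, binSize, chrom, pos, window, maskThreshold) {
    d <- dense[[chrom]]
    if (is.null(d)) return(NA_real_)
    lo <- floor((pos - window / 2) / binSize) - d$gridLo + 1L
    hi <- ceiling((pos + window / 2) / binSize) - d$gridLo
    lo <- max(1L, lo); hi <- min(length(d$W), hi)
    if (hi < lo) return(NA_real_)
    w <- sum(d$W[lo:hi]); c <- sum(d$C[lo:hi])
    if (min(w, c) < maskThreshold || w + c == 0) return(NA_real_)
    (c - w) / (c + w)
}

#' Convert a decoded state path into genomic segments
#'
#' Maximal runs of the same state become segments; the two flat states are
#' merged to FS in the output. Segment start is the start of the first
#' window's central bin; segments tile the decoded portion of the genome.
#' When bin counts are supplied, per-segment RFD is evaluated in
#' \code{endWindow}-bp windows around the left and right extremities,
#' ascending-segment efficiency is derived from them, and flat segments get
#' their mean |RFD| and the high-|RFD| flag (mean |RFD| > 0.6).
#'
#' @param path data.frame from \code{\link{hmmDecode}}.
#' @param profile The \linkS4class{RFDProfile} that generated the track.
#' @param counts Optional \linkS4class{StrandedBinCounts} used for
#'   end-window RFD and efficiency.
#' @param endWindow Width (bp) of the extremity windows (default 5000).
#' @param maskThreshold Per-strand masking threshold for end windows
#'   (default 0: only windows without reads are unassigned).
#' @return A \linkS4class{SegmentSet}.
#' @export
segmentsFromStates <- function(path, profile, counts = NULL,
                               endWindow = 5000L, maskThreshold = 0L) {
    step <- profile@step
    segs <- list()
    merged <- ifelse(path$state %in% c("Flat1", "Flat2"), "FS",
              ifelse(path$state == "Up", "AS",
              ifelse(path$state == "Down", "DS", NA_character_)))
    for (ch in unique(path$chrom)) {
        idx <- which(path$chrom == ch)
        idx <- idx[order(path$position[idx])]
        st <- merged[idx]; pos <- path$position[idx]
        ## break runs at non-contiguous positions as well as state changes
        grp <- cumsum(c(TRUE, st[-1] != st[-length(st)] |
                               is.na(st[-1]) != is.na(st[-length(st)]) |
                               diff(pos) != step))
        for (g in unique(grp)) {
            sel <- which(grp == g)
            if (is.na(st[sel[1L]])) next
            segs[[length(segs) + 1L]] <- data.frame(
                chrom = ch, start = pos[sel[1L]],
                end = pos[sel[length(sel)]] + step,
                state = st[sel[1L]])
        }
    }
    if (length(segs) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(state = character(0), rfdStart = numeric(0),
                               rfdEnd = numeric(0), efficiency = numeric(0),
                               meanAbsRFD = numeric(0), highRFD = logical(0),
                               timingClass = character(0))
        return(new("SegmentSet", segments = gr,
                   windowSize = profile@windowSize, step = step))
    }
    d <- do.call(rbind, segs)
    gr <- GRanges(d$chrom, IRanges(start = d$start + 1L, end = d$end),
                  state = d$state)
    mcols(gr)$rfdStart <- NA_real_
    mcols(gr)$rfdEnd <- NA_real_
    mcols(gr)$efficiency <- NA_real_
    mcols(gr)$meanAbsRFD <- NA_real_
    mcols(gr)$highRFD <- NA
    mcols(gr)$timingClass <- NA_character_
    gr <- sort(gr)
    ## mean |RFD| of profile windows inside each flat segment
    w <- profile@windows
    fs <- which(mcols(gr)$state == "FS")
    if (length(fs)) {
        hits <- findOverlaps(gr[fs], w)
        absR <- tapply(abs(mcols(w)$rfd[S4Vectors::subjectHits(hits)]),
                       S4Vectors::queryHits(hits),
                       mean, na.rm = TRUE)
        mcols(gr)$meanAbsRFD[fs[as.integer(names(absR))]] <- as.numeric(absR)
        mcols(gr)$highRFD[fs] <- !is.na(mcols(gr)$meanAbsRFD[fs]) &
            mcols(gr)$meanAbsRFD[fs] > 0.6
    }
    out <- new("SegmentSet", segments = gr,
               windowSize = profile@windowSize, step = step)
    if (!is.null(counts))
        out <- segmentEfficiency(out, counts, endWindow = endWindow,
                                 maskThreshold = maskThreshold)
    out
}

#' Estimate per-segment end-window RFD and ascending-segment efficiency
#'
#' Efficiency of an ascending segment is half the RFD shift across it, in
#' percent: 100 x (RFD(end) - RFD(start))/2, with RFD evaluated in
#' \code{endWindow}-bp windows around the two extremities, clipped to
#' [0, 100]. It estimates the fraction of cells in which the zone supports
#' an initiation event. Segments with a masked end window keep an
#' unassigned efficiency.
#'
#' @param segset A \linkS4class{SegmentSet}.
#' @param counts A \linkS4class{StrandedBinCounts}.
#' @param endWindow Extremity window width in bp (default 5000).
#' @param maskThreshold Per-strand masking threshold for the end windows
#'   (default 0: only windows without reads leave the efficiency unassigned).
#' @return The \linkS4class{SegmentSet} with \code{rfdStart}, \code{rfdEnd}
#'   and \code{efficiency} (AS rows) filled.
#' @examples
#' ## a full inversion (-1 to +1) is a 100% efficient zone
#' 100 * (1 - (-1)) / 2
#' @export
segmentEfficiency <- function(segset, counts, endWindow = 5000L,
                              maskThreshold = 0L) {
    dense <- .denseCounts(counts)
    bs <- counts@binSize
    gr <- segset@segments
    n <- length(gr)
    rs <- re <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        ch <- as.character(seqnames(gr)[i])
        rs[i] <- .rfdAtPoint(dense, bs, ch, start(gr)[i] - 1L, endWindow,
                             maskThreshold)
        re[i] <- .rfdAtPoint(dense, bs, ch, end(gr)[i], endWindow,
                             maskThreshold)
    }
    mcols(gr)$rfdStart <- rs
    mcols(gr)$rfdEnd <- re
    eff <- rep(NA_real_, n)
    as <- mcols(gr)$state == "AS"
    eff[as] <- pmin(100, pmax(0, 100 * (re[as] - rs[as]) / 2))
    mcols(gr)$efficiency <- eff
    initialize(segset, segments = gr)
}

#' Retain segments reproducibly identified in both replicates
#'
#' A segment is retained iff a segment of the same state in the other
#' replicate overlaps it with reciprocal overlap at least \code{minRecip};
#' the retained coordinates are the intersection of the pair. Loci where the
#' two replicates disagree on the state are dropped from both.
#'
#' @param s1,s2 \linkS4class{SegmentSet}s from the two replicates, computed
#'   with identical parameters.
#' @param minRecip Minimum reciprocal overlap fraction (default 0.5).
#' @return A \linkS4class{SegmentSet} of intersected reproducible segments
#'   (metadata columns from \code{s1}, efficiency left for re-estimation);
#'   the number of dropped segments is in
#'   \code{metadata(segmentRanges(x))$nDropped}.
#' @export
retainReproducible <- function(s1, s2, minRecip = 0.5) {
    if (s1@windowSize != s2@windowSize || s1@step != s2@step)
        stop("replicate segmentations must share parameters")
    g1 <- s1@segments; g2 <- s2@segments
    keep <- list()
    for (stt in c("AS", "DS", "FS")) {
        a <- g1[mcols(g1)$state == stt]
        b <- g2[mcols(g2)$state == stt]
        if (length(a) == 0L || length(b) == 0L) next
        h <- findOverlaps(a, b)
        if (length(h) == 0L) next
        qa <- a[S4Vectors::queryHits(h)]
        qb <- b[S4Vectors::subjectHits(h)]
        ov <- width(pintersect(qa, qb))
        ok <- ov >= minRecip * width(qa) & ov >= minRecip * width(qb)
        if (!any(ok)) next
        inter <- pintersect(qa[ok], qb[ok])
        mcols(inter) <- mcols(qa[ok])[, setdiff(colnames(mcols(qa[ok])),
                                                "hit"), drop = FALSE]
        keep[[stt]] <- inter
    }
    if (length(keep) == 0L) {
        gr <- g1[0]
    } else {
        gr <- sort(unique(do.call(c, unname(keep))))
    }
    metadata(gr)$nDropped <- (length(g1) + length(g2)) - 2L * length(gr)
    new("SegmentSet", segments = gr, windowSize = s1@windowSize,
        step = s1@step)
}
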