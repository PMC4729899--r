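## Expand possibly sparse bin counts to a dense per-chromosome grid.
## Returns list per chrom: gridLo (0-based first bin index), W, C vectors.
.denseCounts <- function(counts) {
    gr <- counts@bins
    bs <- counts@binSize
    out <- list()
    for (ch in unique(as.character(seqnames(gr)))) {
        g <- gr[seqnames(gr) == ch]
        idx <- (start(g) - 1L) %/% bs
        lo <- min(idx); hi <- max(idx)
        W <- C <- integer(hi - lo + 1L)
        W[idx - lo + 1L] <- mcols(g)$W
        C[idx - lo + 1L] <- mcols(g)$C
        out[[ch]] <- list(gridLo = lo, W = W, C = C)
    }
    out
}

.rollSum <- function(x, nb) {
    cs <- c(0, cumsum(as.numeric(x)))
    n <- length(x)
    if (n < nb) return(numeric(0))
    cs[(nb + 1L):(n + 1L)] - cs[1L:(n - nb + 1L)]
}

#' Bin strand-specific read positions into 1-kb stranded counts
#'
#' Each read is assigned to the bin containing its 5' end. By default reads
#' on the + strand increment the Watson count and reads on the - strand the
#' Crick count (so that Crick-strand Okazaki fragments report
#' rightward-moving forks); libraries with inverted chemistry can set
#' \code{flipStrands = TRUE}.
#'
#' @param reads data.frame with columns \code{chrom}, \code{position}
#'   (0-based bp of the 5' end) and \code{strand} ("+"/"-").
#' @param chromLengths Named vector of chromosome lengths (bp).
#' @param binSize Bin width in bp.
#' @param flipStrands Swap the strand-to-count assignment.
#' @return A \linkS4class{StrandedBinCounts} covering every bin of every
#'   chromosome in \code{chromLengths}. Reads beyond the chromosome length
#'   are skipped; their count is reported in a warning and stored in
#'   \code{metadata(binRanges(x))$nSkipped} is not kept -- the warning is the
#'   record.
#' @examples
#' reads <- data.frame(chrom = "chr1", position = c(1500, 1700, 2100),
#'                     strand = c("+", "-", "-"))
#' binStrandedReads(reads, c(chr1 = 4000))
#' @export
binStrandedReads <- function(reads, chromLengths, binSize = 1000L,
                             flipStrands = FALSE) {
    binSize <- as.integer(binSize)
    stopifnot(all(c("chrom", "position", "strand") %in% names(reads)),
              !is.null(names(chromLengths)))
    if (!all(reads$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    bad <- reads$position < 0 |
        reads$position >= chromLengths[as.character(reads$chrom)] |
        !(as.character(reads$chrom) %in% names(chromLengths))
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
        warning(sum(bad), " read(s) outside chromosome bounds skipped")
        reads <- reads[!bad, , drop = FALSE]
    }
    res <- lapply(names(chromLengths), function(ch) {
        nBins <- as.integer(ceiling(chromLengths[[ch]] / binSize))
        W <- C <- integer(nBins)
        r <- reads[reads$chrom == ch, , drop = FALSE]
        if (nrow(r)) {
            idx <- r$position %/% binSize + 1L
            toW <- (r$strand == "+") != flipStrands
            tw <- tabulate(idx[toW], nBins)
            tc <- tabulate(idx[!toW], nBins)
            W <- W + tw; C <- C + tc
        }
        data.frame(chrom = ch, start = (seq_len(nBins) - 1L) * binSize,
                   W = W, C = C)
    })
    d <- do.call(rbind, res)
    StrandedBinCounts(d$chrom, d$start, W = d$W, C = d$C, binSize = binSize)
}

#' Compute a replication fork directionality profile
#'
#' RFD = (C - W)/(C + W) on read counts summed within sliding windows (the
#' per-strand normalization makes the statistic insensitive to copy-number
#' and depth variation). Windows in which either strand total falls below
#' \code{maskThreshold} are masked: their RFD is \code{NA}, never zero.
#'
#' @param counts A \linkS4class{StrandedBinCounts}.
#' @param windowSize Sliding-window width in bp (default 15000, the
#'   resolution/reproducibility compromise used for segmentation).
#' @param step Window step in bp (default 1000).
#' @param maskThreshold Minimum read count per strand per window (default 30).
#' @return An \linkS4class{RFDProfile}; window positions are the central bin
#'   of each full window (windows truncated by the chromosome end are not
#'   emitted).
#' @examples
#' sbc <- StrandedBinCounts("chr1", (0:9) * 1000, W = rep(2L, 10),
#'                          C = rep(6L, 10))
#' rfd(computeRFD(sbc, windowSize = 5000, maskThreshold = 0))
#' @export
computeRFD <- function(counts, windowSize = 15000L, step = 1000L,
                       maskThreshold = 30L) {
    bs <- counts@binSize
    if (windowSize < bs) stop("windowSize must be at least the bin size")
    if (windowSize %% bs != 0 || step %% bs != 0)
        stop("windowSize and step must be multiples of the bin size")
    nb <- as.integer(windowSize / bs)
    stepBins <- as.integer(step / bs)
    offL <- (nb - 1L) %/% 2L
    dense <- .denseCounts(counts)
    pieces <- list()
    for (ch in names(dense)) {
        d <- dense[[ch]]
        sw <- .rollSum(d$W, nb); sc <- .rollSum(d$C, nb)
        if (length(sw) == 0L) { warning("chromosome ", ch,
            " shorter than one window; skipped"); next }
        keep <- seq(1L, length(sw), by = stepBins)
        sw <- sw[keep]; sc <- sc[keep]
        centerIdx <- d$gridLo + offL + keep - 1L   # 0-based bin index
        tot <- sw + sc
        masked <- pmin(sw, sc) < maskThreshold | tot == 0
        rfdv <- ifelse(masked, NA_real_, (sc - sw) / tot)
        if (all(masked)) {
            warning("chromosome ", ch, " is fully masked; dropped")
            next
        }
        pieces[[ch]] <- data.frame(chrom = ch, start = centerIdx * bs,
                                   rfd = rfdv, readsW = sw, readsC = sc,
                                   masked = masked)
    }
    if (length(pieces) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(rfd = numeric(0), readsW = numeric(0),
                               readsC = numeric(0), masked = logical(0))
    } else {
        d <- do.call(rbind, pieces)
        gr <- GRanges(d$chrom, IRanges(start = d$start + 1L, width = bs),
                      rfd = d$rfd, readsW = d$readsW, readsC = d$readsC,
                      masked = d$masked)
    }
    new("RFDProfile", windows = gr, windowSize = as.integer(windowSize),
        step = as.integer(step), maskThreshold = as.integer(maskThreshold))
}

## Align two profiles on chrom+position; returns indices into each.
.sharedWindows <- function(p1, p2) {
    k1 <- paste(as.character(seqnames(p1@windows)), start(p1@windows))
    k2 <- paste(as.character(seqnames(p2@windows)), start(p2@windows))
    m <- match(k1, k2)
    i1 <- which(!is.na(m)); i2 <- m[i1]
    list(i1 = i1, i2 = i2)
}

#' Pearson correlation between two replicate RFD profiles
#'
#' @param p1,p2 \linkS4class{RFDProfile}s computed with identical window
#'   size and step.
#' @return A list with \code{correlation} and \code{nShared}, the number of
#'   positions unmasked in both profiles.
#' @export
replicateCorrelation <- function(p1, p2) {
    if (p1@windowSize != p2@windowSize || p1@step != p2@step)
        stop("profiles must share windowSize and step")
    sh <- .sharedWindows(p1, p2)
    r1 <- rfd(p1)[sh$i1]; r2 <- rfd(p2)[sh$i2]
    ok <- !is.na(r1) & !is.na(r2)
    if (sum(ok) < 2L) stop("fewer than 2 shared unmasked positions")
    list(correlation = stats::cor(r1[ok], r2[ok]), nShared = sum(ok))
}

#' Window-size calibration by replicate slope differences
#'
#' For each window size l, RFD is recomputed on both replicates, the local
#' slope s(n) = RFD(n+1) - RFD(n) is taken on each, and the replicate slope
#' difference d(n) = s1(n) - s2(n) is formed wherever all four windows are
#' unmasked. The cumulative proportion of positions with |d(n)| > x
#' summarizes replicate disagreement; it shrinks as l grows, which is the
#' basis for choosing the segmentation window.
#'
#' @param c1,c2 \linkS4class{StrandedBinCounts} of the two replicates.
#' @param lValues Window sizes (bp) to scan.
#' @param step Window step (bp).
#' @param maskThreshold Per-strand masking threshold.
#' @param xGrid Thresholds x at which the cumulative proportion is reported.
#' @return A data.frame with columns \code{windowSize}, \code{x},
#'   \code{proportion} (of positions with |d| > x) and \code{nPositions}.
#' @export
slopeDifferenceAnalysis <- function(c1, c2,
                                    lValues = c(5, 10, 15, 20, 25, 30) * 1000,
                                    step = 1000L, maskThreshold = 30L,
                                    xGrid = seq(0, 0.3, by = 0.005)) {
    res <- lapply(lValues, function(l) {
        p1 <- computeRFD(c1, windowSize = l, step = step,
                         maskThreshold = maskThreshold)
        p2 <- computeRFD(c2, windowSize = l, step = step,
                         maskThreshold = maskThreshold)
        sh <- .sharedWindows(p1, p2)
        r1 <- rfd(p1)[sh$i1]; r2 <- rfd(p2)[sh$i2]
        ## slopes only between consecutive positions of the same chromosome
        ch <- as.character(seqnames(p1@windows))[sh$i1]
        pos <- start(p1@windows)[sh$i1]
        adj <- ch[-1] == ch[-length(ch)] &
            diff(pos) == step
        s1 <- diff(r1)[adj]; s2 <- diff(r2)[adj]
        d <- s1 - s2
        d <- d[!is.na(d)]
        data.frame(windowSize = l, x = xGrid,
                   proportion = vapply(xGrid,
                       function(x) mean(abs(d) > x), 0),
                   nPositions = length(d))
    })
    do.call(rbind, res)
}
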