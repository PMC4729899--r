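#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

## Central containers. Genomic coordinates are stored 1-based closed inside
## GRanges (the Bioconductor convention); every external text interface
## (BED/bedGraph/TSV, constructors taking `binStart`) is 0-based half-open.

#' Watson/Crick read counts per genomic bin
#'
#' Holds strand-resolved Okazaki-fragment read counts in fixed-width bins
#' (default 1 kb). Crick-strand reads report rightward-moving forks and
#' Watson-strand reads leftward-moving forks.
#'
#' @slot bins A \link[GenomicRanges]{GRanges} of bins with integer metadata
#'   columns \code{W} and \code{C}.
#' @slot binSize Bin width in bp.
#' @exportClass StrandedBinCounts
setClass("StrandedBinCounts",
    representation(bins = "GRanges", binSize = "integer"))

setValidity("StrandedBinCounts", function(object) {
    m <- mcols(object@bins)
    if (!all(c("W", "C") %in% colnames(m)))
        return("bins must carry 'W' and 'C' metadata columns")
    if (any(m$W < 0) || any(m$C < 0))
        return("counts must be non-negative")
    if (any(m$W != round(m$W)) || any(m$C != round(m$C)))
        return("counts must be integral")
    if (length(object@binSize) != 1L || object@binSize < 1L)
        return("binSize must be a single positive integer")
    if (any(width(object@bins) != object@binSize))
        return("all bins must have width binSize")
    if (is.unsorted(order(as.integer(seqnames(object@bins)), start(object@bins))))
        return("bins must be sorted")
    sp <- split(start(object@bins), as.character(seqnames(object@bins)))
    if (any(vapply(sp, anyDuplicated, 0L) > 0L))
        return("bins must be unique per chromosome")
    TRUE
})

#' Construct a StrandedBinCounts object
#'
#' @param chrom Character vector of chromosome names.
#' @param binStart Integer vector of 0-based bin start positions (bp),
#'   multiples of \code{binSize}.
#' @param W,C Non-negative integer read counts on the Watson and Crick strand.
#' @param binSize Bin width in bp (default 1000).
#' @return A \linkS4class{StrandedBinCounts} object.
#' @examples
#' sbc <- StrandedBinCounts("chr1", c(0, 1000), W = c(3L, 1L), C = c(0L, 5L))
#' rfd(computeRFD(sbc, windowSize = 1000, maskThreshold = 0))
#' @export
StrandedBinCounts <- function(chrom, binStart, W, C, binSize = 1000L) {
    binSize <- as.integer(binSize)
    if (any(binStart %% binSize != 0))
        stop("bin starts must be multiples of binSize")
    gr <- GRanges(chrom, IRanges(start = binStart + 1L, width = binSize),
                  W = as.integer(round(W)), C = as.integer(round(C)))
    gr <- sort(gr)
    new("StrandedBinCounts", bins = gr, binSize = binSize)
}

#' Replication fork directionality profile
#'
#' RFD = (C - W)/(C + W) computed on read counts summed in sliding windows;
#' +1 means 100\% rightward-moving forks, -1 means 100\% leftward.
#' Windows where either strand total falls below \code{maskThreshold} are
#' masked (RFD is \code{NA}, never zero).
#'
#' @slot windows A \link[GenomicRanges]{GRanges} of window-center bins with
#'   metadata columns \code{rfd}, \code{readsW}, \code{readsC}, \code{masked}.
#' @slot windowSize,step Window width and step in bp.
#' @slot maskThreshold Minimum per-strand window total.
#' @exportClass RFDProfile
setClass("RFDProfile",
    representation(windows = "GRanges", windowSize = "integer",
                   step = "integer", maskThreshold = "integer"))

setValidity("RFDProfile", function(object) {
    m <- mcols(object@windows)
    need <- c("rfd", "readsW", "readsC", "masked")
    if (!all(need %in% colnames(m)))
        return(paste("windows must carry", paste(need, collapse = ", ")))
    ok <- !m$masked
    if (any(abs(m$rfd[ok]) > 1 + 1e-12, na.rm = TRUE))
        return("unmasked RFD values must lie in [-1, 1]")
    if (any(!is.na(m$rfd[m$masked])))
        return("masked windows must carry NA rfd, not a number")
    TRUE
})

#' HMM observation track of RFD increments
#'
#' Per-position increments \eqn{\Delta RFD_n = (RFD_{n+1} - RFD_n)/2} between
#' adjacent windows, optionally encoded into five equal-frequency quantile
#' codes used as the categorical HMM observations.
#'
#' @slot chrom Chromosome per position.
#' @slot position 0-based window-center bin start (bp) of window n.
#' @slot delta Numeric increments, \code{NA} where either window is masked.
#' @slot code Integer quantile codes 1..5 (\code{NA} before encoding/missing).
#' @slot step Window step in bp.
#' @exportClass DeltaRFDTrack
setClass("DeltaRFDTrack",
    representation(chrom = "character", position = "numeric",
                   delta = "numeric", code = "integer", step = "integer"))

setValidity("DeltaRFDTrack", function(object) {
    n <- length(object@delta)
    if (length(object@chrom) != n || length(object@position) != n ||
        length(object@code) != n)
        return("chrom, position, delta, code must have equal length")
    if (any(!is.na(object@code) & (object@code < 1L | object@code > 5L)))
        return("codes must be in 1..5")
    TRUE
})

#' Segmentation of an RFD profile
#'
#' Maximal runs of the decoded HMM states, merged to three biological states:
#' AS (ascending, predominant initiation), DS (descending, predominant
#' termination) and FS (flat, constant directionality).
#'
#' @slot segments A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{state} ("AS","DS","FS"), \code{rfdStart}, \code{rfdEnd} (RFD in
#'   end windows), \code{efficiency} (percent, AS only), \code{meanAbsRFD}
#'   (FS only), \code{highRFD} (FS with mean |RFD| > 0.6), \code{timingClass}.
#' @slot windowSize,step RFD window parameters used for the segmentation.
#' @exportClass SegmentSet
setClass("SegmentSet",
    representation(segments = "GRanges", windowSize = "integer",
                   step = "integer"))

setValidity("SegmentSet", function(object) {
    m <- mcols(object@segments)
    if (!"state" %in% colnames(m)) return("segments must carry 'state'")
    if (!all(m$state %in% c("AS", "DS", "FS")))
        return("state must be one of AS, DS, FS")
    gr <- object@segments
    for (ch in unique(as.character(seqnames(gr)))) {
        g <- gr[seqnames(gr) == ch]
        if (length(g) > 1L) {
            o <- order(start(g))
            if (any(start(g)[o][-1L] <= end(g)[o][-length(g)]))
                return("segments must be non-overlapping within a chromosome")
        }
    }
    TRUE
})

#' Ground truth of a stochastic replication simulation
#'
#' @slot config The \code{simulationConfig} list used.
#' @slot bins A \link[GenomicRanges]{GRanges} of genomic bins.
#' @slot rfd Per-bin true RFD: (cells replicating the bin rightward minus
#'   leftward)/nCells.
#' @slot mrt Per-bin mean replication time (minutes).
#' @slot rightCount Per-bin number of cells replicating the bin rightward.
#' @slot events Per-cell data.frames of realized initiation events
#'   (columns: position bp, time min, source "zone<i>" or "background").
#' @slot zoneStats data.frame per zone: scheduled and realized firing counts.
#' @slot tS Total S-phase duration (max replication time over cells/bins).
#' @slot nCells Number of simulated cells.
#' @slot nResampled Cells rejected (no initiation) and redrawn.
#' @exportClass ReplicationTruth
setClass("ReplicationTruth",
    representation(config = "list", bins = "GRanges", rfd = "numeric",
                   mrt = "numeric", rightCount = "integer", events = "list",
                   zoneStats = "data.frame", tS = "numeric",
                   nCells = "integer", nResampled = "integer"))

setValidity("ReplicationTruth", function(object) {
    n <- length(object@bins)
    if (length(object@rfd) != n || length(object@mrt) != n ||
        length(object@rightCount) != n)
        return("per-bin slots must match the number of bins")
    if (any(abs(object@rfd) > 1 + 1e-12)) return("true RFD must lie in [-1,1]")
    if (any(!is.finite(object@mrt))) return("MRT must be finite for all bins")
    TRUE
})

#' Multi-fraction replication timing profile
#'
#' Per-bin read enrichment across six equal S-phase compartments, and the
#' interpolated S50 (fraction of S phase at which half the cell population
#' has replicated the bin).
#'
#' @slot bins A \link[GenomicRanges]{GRanges} of bins.
#' @slot enrichment Numeric matrix (bins x 6) of non-negative enrichments.
#' @slot s50 Numeric vector in (0,1), \code{NA} where unassigned.
#' @exportClass TimingProfile
setClass("TimingProfile",
    representation(bins = "GRanges", enrichment = "matrix", s50 = "numeric"))

setValidity("TimingProfile", function(object) {
    if (ncol(object@enrichment) != 6L)
        return("enrichment must have six columns (S-phase compartments)")
    if (nrow(object@enrichment) != length(object@bins))
        return("enrichment rows must match bins")
    if (any(object@enrichment < 0, na.rm = TRUE))
        return("enrichments must be non-negative")
    if (any(object@s50 <= 0 | object@s50 >= 1, na.rm = TRUE))
        return("s50 must lie strictly inside (0,1) where assigned")
    TRUE
})

#' Construct a TimingProfile
#'
#' @param chrom Chromosome names.
#' @param binStart 0-based bin starts (bp).
#' @param enrichment Matrix with one row per bin and six columns, the read
#'   enrichment in each S-phase compartment (earliest first; when importing
#'   real six-fraction Repli-seq, order the columns from the earliest to the
#'   latest fraction).
#' @param binSize Bin width in bp.
#' @return A \linkS4class{TimingProfile} (S50 unassigned until
#'   \code{\link{computeS50}} is called).
#' @export
TimingProfile <- function(chrom, binStart, enrichment, binSize = 1000L) {
    enrichment <- as.matrix(enrichment)
    gr <- GRanges(chrom, IRanges(start = binStart + 1L, width = binSize))
    new("TimingProfile", bins = gr, enrichment = enrichment,
        s50 = rep(NA_real_, length(gr)))
}
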