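#' Accessors for okseqr classes
#'
#' Small accessor generics: \code{binSize}, \code{watsonCounts},
#' \code{crickCounts}, \code{rfd}, \code{isMasked}, \code{windowSize},
#' \code{windowStep}, \code{segmentRanges}, \code{segmentStates},
#' \code{efficiencies}, \code{timingClasses}, \code{trueRFD}, \code{trueMRT},
#' \code{sPhaseDuration}, \code{initiationEvents}, \code{zoneStats},
#' \code{s50}, \code{enrichmentMatrix}, \code{binRanges}.
#'
#' @param x An okseqr object.
#' @return The slot content described by the accessor name.
#' @name okseqr-accessors
#' @examples
#' sbc <- StrandedBinCounts("chr1", 0, W = 10L, C = 30L)
#' watsonCounts(sbc); crickCounts(sbc); binSize(sbc)
NULL

#' @rdname okseqr-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname okseqr-accessors
#' @export
setMethod("binSize", "StrandedBinCounts", function(x) x@binSize)
#' @rdname okseqr-accessors
#' @export
setMethod("binSize", "ReplicationTruth", function(x) as.integer(x@config$binSize))

#' @rdname okseqr-accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))
#' @rdname okseqr-accessors
#' @export
setMethod("binRanges", "StrandedBinCounts", function(x) granges(x@bins))
#' @rdname okseqr-accessors
#' @export
setMethod("binRanges", "ReplicationTruth", function(x) x@bins)
#' @rdname okseqr-accessors
#' @export
setMethod("binRanges", "TimingProfile", function(x) x@bins)
#' @rdname okseqr-accessors
#' @export
setMethod("binRanges", "RFDProfile", function(x) granges(x@windows))

#' @rdname okseqr-accessors
#' @export
setGeneric("watsonCounts", function(x) standardGeneric("watsonCounts"))
#' @rdname okseqr-accessors
#' @export
setMethod("watsonCounts", "StrandedBinCounts", function(x) mcols(x@bins)$W)

#' @rdname okseqr-accessors
#' @export
setGeneric("crickCounts", function(x) standardGeneric("crickCounts"))
#' @rdname okseqr-accessors
#' @export
setMethod("crickCounts", "StrandedBinCounts", function(x) mcols(x@bins)$C)

#' @rdname okseqr-accessors
#' @export
setGeneric("rfd", function(x) standardGeneric("rfd"))
#' @rdname okseqr-accessors
#' @export
setMethod("rfd", "RFDProfile", function(x) mcols(x@windows)$rfd)

#' @rdname okseqr-accessors
#' @export
setGeneric("isMasked", function(x) standardGeneric("isMasked"))
#' @rdname okseqr-accessors
#' @export
setMethod("isMasked", "RFDProfile", function(x) mcols(x@windows)$masked)

#' @rdname okseqr-accessors
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname okseqr-accessors
#' @export
setMethod("windowSize", "RFDProfile", function(x) x@windowSize)
#' @rdname okseqr-accessors
#' @export
setMethod("windowSize", "SegmentSet", function(x) x@windowSize)

#' @rdname okseqr-accessors
#' @export
setGeneric("windowStep", function(x) standardGeneric("windowStep"))
#' @rdname okseqr-accessors
#' @export
setMethod("windowStep", "RFDProfile", function(x) x@step)
#' @rdname okseqr-accessors
#' @export
setMethod("windowStep", "SegmentSet", function(x) x@step)

#' @rdname okseqr-accessors
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))
#' @rdname okseqr-accessors
#' @export
setMethod("segmentRanges", "SegmentSet", function(x) x@segments)

#' @rdname okseqr-accessors
#' @export
setGeneric("segmentStates", function(x) standardGeneric("segmentStates"))
#' @rdname okseqr-accessors
#' @export
setMethod("segmentStates", "SegmentSet",
    function(x) mcols(x@segments)$state)

#' @rdname okseqr-accessors
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))
#' @rdname okseqr-accessors
#' @export
setMethod("efficiencies", "SegmentSet",
    function(x) mcols(x@segments)$efficiency)

#' @rdname okseqr-accessors
#' @export
setGeneric("timingClasses", function(x) standardGeneric("timingClasses"))
#' @rdname okseqr-accessors
#' @export
setMethod("timingClasses", "SegmentSet",
    function(x) mcols(x@segments)$timingClass)

#' @rdname okseqr-accessors
#' @export
setGeneric("trueRFD", function(x) standardGeneric("trueRFD"))
#' @rdname okseqr-accessors
#' @export
setMethod("trueRFD", "ReplicationTruth", function(x) x@rfd)

#' @rdname okseqr-accessors
#' @export
setGeneric("trueMRT", function(x) standardGeneric("trueMRT"))
#' @rdname okseqr-accessors
#' @export
setMethod("trueMRT", "ReplicationTruth", function(x) x@mrt)

#' @rdname okseqr-accessors
#' @export
setGeneric("sPhaseDuration", function(x) standardGeneric("sPhaseDuration"))
#' @rdname okseqr-accessors
#' @export
setMethod("sPhaseDuration", "ReplicationTruth", function(x) x@tS)

#' @rdname okseqr-accessors
#' @export
setGeneric("initiationEvents", function(x) standardGeneric("initiationEvents"))
#' @rdname okseqr-accessors
#' @export
setMethod("initiationEvents", "ReplicationTruth", function(x) x@events)

#' @rdname okseqr-accessors
#' @export
setGeneric("zoneStats", function(x) standardGeneric("zoneStats"))
#' @rdname okseqr-accessors
#' @export
setMethod("zoneStats", "ReplicationTruth", function(x) x@zoneStats)

#' @rdname okseqr-accessors
#' @export
setGeneric("s50", function(x) standardGeneric("s50"))
#' @rdname okseqr-accessors
#' @export
setMethod("s50", "TimingProfile", function(x) x@s50)

#' @rdname okseqr-accessors
#' @export
setGeneric("enrichmentMatrix", function(x) standardGeneric("enrichmentMatrix"))
#' @rdname okseqr-accessors
#' @export
setMethod("enrichmentMatrix", "TimingProfile", function(x) x@enrichment)

setMethod("show", "StrandedBinCounts", function(object) {
    cat("StrandedBinCounts:", length(object@bins), "bins of",
        object@binSize, "bp on",
        length(unique(as.character(seqnames(object@bins)))), "chromosome(s)\n")
    cat("  total W =", sum(mcols(object@bins)$W),
        " total C =", sum(mcols(object@bins)$C), "\n")
})

setMethod("show", "RFDProfile", function(object) {
    m <- mcols(object@windows)
    cat("RFDProfile:", length(object@windows), "windows (",
        object@windowSize, "bp, step", object@step, "bp, mask <",
        object@maskThreshold, "reads/strand)\n")
    cat("  masked:", sum(m$masked), " mean RFD:",
        round(mean(m$rfd, na.rm = TRUE), 4), "\n")
})

setMethod("show", "DeltaRFDTrack", function(object) {
    cat("DeltaRFDTrack:", length(object@delta), "positions, ",
        sum(is.na(object@delta)), "missing;",
        if (all(is.na(object@code))) "not yet quantile-encoded" else
            "quantile-encoded", "\n")
})

setMethod("show", "SegmentSet", function(object) {
    st <- mcols(object@segments)$state
    cat("SegmentSet:", length(object@segments), "segments (AS:",
        sum(st == "AS"), " DS:", sum(st == "DS"), " FS:", sum(st == "FS"),
        ")\n")
})

setMethod("show", "ReplicationTruth", function(object) {
    cat("ReplicationTruth:", length(object@bins), "bins,",
        object@nCells, "cells, S duration", round(object@tS, 1), "min\n")
    cat("  zones:", nrow(object@zoneStats), " resampled cells:",
        object@nResampled, "\n")
})

setMethod("show", "TimingProfile", function(object) {
    cat("TimingProfile:", length(object@bins), "bins;",
        sum(!is.na(object@s50)), "with assigned S50\n")
})
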