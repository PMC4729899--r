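## Centered rolling mean with shrinking edge windows (per column).
.rollMeanEdge <- function(x, nb) {
    if (nb <= 1L) return(x)
    n <- length(x)
    offL <- (nb - 1L) %/% 2L; offR <- nb - 1L - offL
    cs <- c(0, cumsum(x))
    lo <- pmax(1L, seq_len(n) - offL); hi <- pmin(n, seq_len(n) + offR)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compute S50 replication timing by linear interpolation
#'
#' Per bin, the six compartment enrichments are normalized to sum one; the
#' cumulative replicated fraction is taken piecewise-linear within each
#' compartment (compartment i spans ((i-1)/6, i/6] of S phase, mass uniform
#' within it) and S50 is the S-phase fraction at which the cumulative curve
#' reaches 0.5. Bins with all-zero enrichment stay unassigned.
#'
#' @param tp A \linkS4class{TimingProfile}.
#' @param smoothWindow Optional centered sliding-window width (bp) applied to
#'   each compartment enrichment before interpolation (0 = none; genome-scale
#'   analyses of real six-fraction data conventionally smooth over 100 kb).
#' @return The \linkS4class{TimingProfile} with \code{s50} filled.
#' @examples
#' tp <- TimingProfile("chr1", c(0, 1000),
#'                     rbind(rep(1/6, 6), c(1, 0, 0, 0, 0, 0)))
#' s50(computeS50(tp))   # 0.5 and 1/12
#' @export
computeS50 <- function(tp, smoothWindow = 0L) {
    en <- tp@enrichment
    if (smoothWindow > 0L) {
        bs <- unique(width(tp@bins))[1L]
        nb <- max(1L, as.integer(round(smoothWindow / bs)))
        for (ch in unique(as.character(seqnames(tp@bins)))) {
            sel <- which(as.character(seqnames(tp@bins)) == ch)
            sel <- sel[order(start(tp@bins)[sel])]
            for (k in 1:6) en[sel, k] <- .rollMeanEdge(en[sel, k], nb)
        }
    }
    tot <- rowSums(en)
    s50v <- rep(NA_real_, nrow(en))
    ok <- which(tot > 0)
    if (length(ok)) {
        e <- en[ok, , drop = FALSE] / tot[ok]
        cum <- t(apply(e, 1L, cumsum))
        firstI <- max.col(cum >= 0.5 - 1e-12, ties.method = "first")
        ri <- seq_along(ok)
        prev <- ifelse(firstI == 1L, 0, cum[cbind(ri, pmax(1L, firstI - 1L))])
        ei <- e[cbind(ri, firstI)]
        s50v[ok] <- (firstI - 1L) / 6 + (0.5 - prev) / ei / 6
    }
    initialize(tp, enrichment = en, s50 = s50v)
}

#' Classify S50 values into S-phase periods
#'
#' S1 (0.1 < S50 <= 0.3), S2 (0.3 < S50 <= 0.5), S3 (0.5 < S50 <= 0.7),
#' S4 (0.7 < S50 <= 0.9); values at or below 0.1 or above 0.9 (and missing
#' values) are "unassigned".
#'
#' @param s50 Numeric vector of S50 values.
#' @return Character vector of classes.
#' @examples
#' timingClass(c(0.2, 0.3, 0.95))
#' @export
timingClass <- function(s50) {
    cl <- as.character(cut(s50, breaks = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           labels = c("S1", "S2", "S3", "S4"), right = TRUE))
    cl[is.na(cl)] <- "unassigned"
    cl
}

#' Assign timing classes to segments
#'
#' Each segment receives the class of its mean S50 over overlapping bins.
#'
#' @param segset A \linkS4class{SegmentSet}.
#' @param tp A \linkS4class{TimingProfile} with S50 computed.
#' @return The \linkS4class{SegmentSet} with \code{timingClass} filled.
#' @export
assignTimingClasses <- function(segset, tp) {
    gr <- segset@segments
    h <- findOverlaps(gr, tp@bins)
    m <- tapply(tp@s50[S4Vectors::subjectHits(h)],
                S4Vectors::queryHits(h), mean, na.rm = TRUE)
    cls <- rep(NA_character_, length(gr))
    cls[as.integer(names(m))] <- timingClass(as.numeric(m))
    mcols(gr)$timingClass <- cls
    initialize(segset, segments = gr)
}

#' Consistency between mean replication timing and RFD
#'
#' At constant fork speed v the spatial derivative of mean replication
#' timing equals RFD/v. This compares the centered finite difference
#' dMRT/dx with RFD/v on aligned bins and summarizes the residuals.
#'
#' @param x A \linkS4class{ReplicationTruth}, or a numeric MRT vector
#'   (minutes per bin).
#' @param rfdValues Per-bin RFD (ignored when \code{x} is a truth object).
#' @param forkSpeed v in kb/min (default: value stored in the truth).
#' @param dx Bin width in kb (default: from the truth).
#' @return A list with \code{residuals} (min/kb), \code{correlation}
#'   (\code{NA} when either series is constant), \code{rmse} and \code{n}.
#' @export
mrtRfdConsistency <- function(x, rfdValues = NULL, forkSpeed = NULL,
                              dx = NULL) {
    if (is(x, "ReplicationTruth")) {
        mrt <- x@mrt
        rfdValues <- x@rfd
        if (is.null(forkSpeed)) forkSpeed <- x@config$forkSpeed
        if (is.null(dx)) dx <- x@config$binSize / 1000
    } else mrt <- as.numeric(x)
    n <- length(mrt)
    if (n < 3L) stop("need at least 3 aligned bins")
    stopifnot(length(rfdValues) == n, forkSpeed > 0, dx > 0)
    i <- 2:(n - 1L)
    dmdx <- (mrt[i + 1L] - mrt[i - 1L]) / (2 * dx)
    expected <- rfdValues[i] / forkSpeed
    res <- dmdx - expected
    corr <- if (stats::sd(dmdx) == 0 || stats::sd(expected) == 0) NA_real_
            else stats::cor(dmdx, expected)
    list(residuals = res, correlation = corr,
         rmse = sqrt(mean(res^2)), n = length(i))
}

#' Mean profile along rescaled domains
#'
#' Rescales each domain to [0,1], interpolates the profile at \code{nPoints}
#' common abscissae and averages across domains with the standard error of
#' the mean. This is how N-shaped RFD gradients along megabase replication
#' domains are summarized.
#'
#' @param x An \linkS4class{RFDProfile} (unmasked windows are used) or a
#'   data.frame with columns \code{chrom}, \code{position} (bp),
#'   \code{value}.
#' @param domains A \link[GenomicRanges]{GRanges} or data.frame with
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open bp).
#' @param nPoints Number of interpolation points.
#' @return A data.frame with \code{x} (0..1), \code{mean}, \code{sem};
#'   attribute \code{nDomains} gives the number of domains used (domains
#'   with fewer than two data points are skipped and counted in attribute
#'   \code{nSkipped}).
#' @export
rescaledDomainProfile <- function(x, domains, nPoints = 101L) {
    if (is(x, "RFDProfile")) {
        w <- x@windows
        df <- data.frame(chrom = as.character(seqnames(w)),
                         position = start(w) - 1L + width(w) / 2,
                         value = mcols(w)$rfd)
        df <- df[!is.na(df$value), , drop = FALSE]
    } else df <- x
    if (is(domains, "GRanges")) {
        dom <- data.frame(chrom = as.character(seqnames(domains)),
                          start = start(domains) - 1L, end = end(domains))
    } else dom <- domains
    grid <- seq(0, 1, length.out = nPoints)
    rows <- list(); skipped <- 0L
    for (i in seq_len(nrow(dom))) {
        sel <- df$chrom == dom$chrom[i] & df$position >= dom$start[i] &
            df$position < dom$end[i]
        if (sum(sel) < 2L || dom$end[i] - dom$start[i] <= 0) {
            skipped <- skipped + 1L; next
        }
        rel <- (df$position[sel] - dom$start[i]) /
            (dom$end[i] - dom$start[i])
        rows[[length(rows) + 1L]] <-
            stats::approx(rel, df$value[sel], xout = grid, rule = 2)$y
    }
    if (length(rows) == 0L) stop("no usable domains")
    m <- do.call(rbind, rows)
    sem <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) / sqrt(nrow(m))
           else rep(0, ncol(m))
    out <- data.frame(x = grid, mean = colMeans(m), sem = sem)
    attr(out, "nDomains") <- nrow(m)
    attr(out, "nSkipped") <- skipped
    out
}
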