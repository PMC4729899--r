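## Text interfaces are 0-based half-open (BED/bedGraph conventions); RFD is
## printed to 4 decimals.

.checkFile <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    path
}

#' Read and write stranded bin counts (4-column TSV)
#'
#' The format is tab-separated \code{chrom, start, W, C} with 0-based bin
#' starts and no header.
#'
#' @param path File path.
#' @param binSize Bin width in bp.
#' @return \code{readStrandedBinCounts}: a \linkS4class{StrandedBinCounts}.
#' @export
readStrandedBinCounts <- function(path, binSize = 1000L) {
    d <- utils::read.table(.checkFile(path), sep = "\t",
                           col.names = c("chrom", "start", "W", "C"),
                           colClasses = c("character", "numeric", "integer",
                                          "integer"))
    StrandedBinCounts(d$chrom, d$start, W = d$W, C = d$C, binSize = binSize)
}

#' @rdname readStrandedBinCounts
#' @param x A \linkS4class{StrandedBinCounts}.
#' @export
writeStrandedBinCounts <- function(x, path) {
    d <- data.frame(chrom = as.character(seqnames(x@bins)),
                    start = start(x@bins) - 1L,
                    W = mcols(x@bins)$W, C = mcols(x@bins)$C)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write an RFD profile as bedGraph
#'
#' Masked windows are omitted from the output; values carry 4 decimals.
#'
#' @param profile An \linkS4class{RFDProfile}.
#' @param path Output path.
#' @export
writeRFDBedGraph <- function(profile, path) {
    w <- profile@windows
    ok <- !mcols(w)$masked
    d <- data.frame(chrom = as.character(seqnames(w))[ok],
                    start = start(w)[ok] - 1L, end = end(w)[ok],
                    value = sprintf("%.4f", mcols(w)$rfd[ok]))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a 4-column bedGraph into a data.frame
#'
#' @param path File path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{value} (0-based half-open).
#' @export
readBedGraph <- function(path) {
    utils::read.table(.checkFile(path), sep = "\t",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"))
}

#' Write simulation truth tracks as bedGraph
#'
#' @param truth A \linkS4class{ReplicationTruth}.
#' @param what "rfd" or "mrt".
#' @param path Output path.
#' @export
writeTruthBedGraph <- function(truth, what = c("rfd", "mrt"), path) {
    what <- match.arg(what)
    v <- if (what == "rfd") truth@rfd else truth@mrt
    d <- data.frame(chrom = as.character(seqnames(truth@bins)),
                    start = start(truth@bins) - 1L, end = end(truth@bins),
                    value = sprintf("%.4f", v))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write segments as a BED6-like file
#'
#' Columns: chrom, start, end, state, score, strand("."). The score is the
#' efficiency (percent) for ascending segments and 1000 x mean |RFD| for
#' flat segments, 0 otherwise.
#'
#' @param segset A \linkS4class{SegmentSet}.
#' @param path Output path.
#' @export
writeSegments <- function(segset, path) {
    gr <- segset@segments
    m <- mcols(gr)
    score <- ifelse(m$state == "AS" & !is.na(m$efficiency),
                    round(m$efficiency, 1),
             ifelse(m$state == "FS" & !is.na(m$meanAbsRFD),
                    round(1000 * m$meanAbsRFD), 0))
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    name = m$state, score = score, strand = ".")
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read/write a gene annotation (BED6 + expression TSV)
#'
#' @param bedPath BED6 file (chrom, start, end, name, score, strand).
#' @param exprPath Two-column TSV (gene name, expression).
#' @param activeThreshold Expression above which a gene is flagged active.
#' @return A gene \link[GenomicRanges]{GRanges} with \code{name},
#'   \code{expression}, \code{active}.
#' @export
readGeneAnnotation <- function(bedPath, exprPath, activeThreshold = 0) {
    b <- utils::read.table(.checkFile(bedPath), sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
    e <- utils::read.table(.checkFile(exprPath), sep = "\t",
                           col.names = c("name", "expression"))
    expr <- e$expression[match(b$name, e$name)]
    expr[is.na(expr)] <- 0
    GRanges(b$chrom, IRanges(start = b$start + 1L, end = b$end),
            strand = b$strand, name = b$name, expression = expr,
            active = expr > activeThreshold)
}

#' @rdname readGeneAnnotation
#' @param genes Gene \link[GenomicRanges]{GRanges} with \code{name} and
#'   \code{expression}.
#' @export
writeGeneAnnotation <- function(genes, bedPath, exprPath) {
    nm <- mcols(genes)$name
    if (is.null(nm)) nm <- paste0("gene", seq_along(genes))
    d <- data.frame(chrom = as.character(seqnames(genes)),
                    start = start(genes) - 1L, end = end(genes),
                    name = nm, score = 0,
                    strand = as.character(strand(genes)))
    utils::write.table(d, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(nm, mcols(genes)$expression), exprPath,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(bedPath)
}

#' Read a six-fraction timing table
#'
#' Tab-separated \code{chrom, start, e1..e6} (earliest S-phase fraction
#' first; no header).
#'
#' @param path File path.
#' @param binSize Bin width in bp.
#' @return A \linkS4class{TimingProfile}.
#' @export
readTimingProfile <- function(path, binSize = 1000L) {
    d <- utils::read.table(.checkFile(path), sep = "\t")
    if (ncol(d) != 8L) stop("expected 8 columns: chrom, start, e1..e6")
    TimingProfile(d[[1L]], d[[2L]], as.matrix(d[, 3:8]), binSize = binSize)
}

#' Read Hi-C flank contact counts and compute the directionality index
#'
#' Three tab-separated columns: bin start (bp, 0-based, 40-kb bins by
#' convention), upstream contacts A, downstream contacts B.
#'
#' @param path File path.
#' @return data.frame with \code{start}, \code{A}, \code{B}, \code{E},
#'   \code{di}.
#' @export
readDICounts <- function(path) {
    d <- utils::read.table(.checkFile(path), sep = "\t",
                           col.names = c("start", "A", "B"))
    d$E <- (d$A + d$B) / 2
    d$di <- directionalityIndex(d$A, d$B)
    d
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{simulationConfig}};
#' \code{zones} is a list of mappings with keys \code{start}, \code{end},
#' \code{firingProbability}, \code{timeMean}, \code{timeSd}.
#'
#' @param path YAML file path.
#' @return A \code{\link{simulationConfig}}.
#' @export
readSimulationConfig <- function(path) {
    y <- yaml::read_yaml(.checkFile(path))
    zones <- do.call(rbind, lapply(y$zones, as.data.frame))
    y$zones <- zones
    do.call(simulationConfig, y)
}

.logStage <- function(log, stage, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
                   paste0(..., collapse = ""))
    message(line)
    if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
    invisible(NULL)
}

#' Run the full OK-seq analysis pipeline
#'
#' Executes, in order: reading of replicate stranded bin counts, RFD
#' computation per replicate and on pooled counts, increment track and
#' quantile coding, HMM decoding, segment construction, replicate
#' retention, efficiency estimation on the pooled counts, optional timing
#' classification and gene-context typing, and writes bedGraph/BED/TSV
#' outputs plus a run log.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \code{countFiles} (>= 1 paths of 4-column count TSVs), \code{outDir};
#'   optional \code{windowSize} (15000), \code{step} (1000),
#'   \code{maskThreshold} (30), \code{endWindow} (5000), \code{gapMax}
#'   (100000), \code{minRecip} (0.5), \code{flank} (20000),
#'   \code{activeThreshold} (0), \code{binSize} (1000), \code{hmmParams},
#'   \code{timingFile}, \code{geneBed} + \code{geneExpr}, \code{seed} (1).
#' @return (Invisibly) a list with the pooled profile, per-replicate
#'   segment sets, the retained \linkS4class{SegmentSet} and, when inputs
#'   allow, AS types and timing classes.
#' @export
runOkseqPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(.checkFile(config))
    dflt <- list(windowSize = 15000L, step = 1000L, maskThreshold = 30L,
                 endWindow = 5000L, endMaskThreshold = 0L,
                 gapMax = 100000, minRecip = 0.5,
                 flank = 20000L, activeThreshold = 0, binSize = 1000L,
                 seed = 1L, hmmParams = NULL)
    for (k in names(dflt)) if (is.null(config[[k]])) config[[k]] <- dflt[[k]]
    if (is.null(config$countFiles) || length(config$countFiles) < 1L)
        stop("config$countFiles must list at least one count file")
    if (is.null(config$outDir)) stop("config$outDir is required")
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(config$outDir, "run.log")
    cat("okseqr ", as.character(utils::packageVersion("okseqr")),
        " seed=", config$seed, "\n", sep = "", file = log)
    for (k in c("windowSize", "step", "maskThreshold", "endWindow",
                "gapMax", "minRecip", "flank"))
        cat("param ", k, "=", config[[k]], "\n", sep = "", file = log,
            append = TRUE)
    set.seed(config$seed)
    params <- if (is.null(config$hmmParams)) defaultHMMParameters()
              else config$hmmParams

    counts <- lapply(config$countFiles, function(f) {
        x <- readStrandedBinCounts(.checkFile(f), binSize = config$binSize)
        .logStage(log, "read", f, ": ", length(x@bins), " bins")
        x
    })
    pooledDf <- Reduce(function(a, b) {
        stopifnot(length(a@bins) == length(b@bins))
        StrandedBinCounts(as.character(seqnames(a@bins)),
                          start(a@bins) - 1L,
                          W = mcols(a@bins)$W + mcols(b@bins)$W,
                          C = mcols(a@bins)$C + mcols(b@bins)$C,
                          binSize = a@binSize)
    }, counts)
    profiles <- lapply(counts, computeRFD, windowSize = config$windowSize,
                       step = config$step,
                       maskThreshold = config$maskThreshold)
    pooledProfile <- computeRFD(pooledDf, windowSize = config$windowSize,
                                step = config$step,
                                maskThreshold = config$maskThreshold)
    .logStage(log, "rfd", length(pooledProfile@windows),
              " pooled windows, ", sum(isMasked(pooledProfile)), " masked")
    segsets <- lapply(seq_along(profiles), function(i) {
        tr <- quantileEncode(deltaRFD(profiles[[i]]))
        path <- hmmDecode(tr, params = params, gapMax = config$gapMax)
        ss <- segmentsFromStates(path, profiles[[i]], counts = counts[[i]],
                                 endWindow = config$endWindow,
                                 maskThreshold = config$endMaskThreshold)
        .logStage(log, "segment", "replicate ", i, ": ",
                  length(ss@segments), " segments")
        writeSegments(ss, file.path(config$outDir,
                                    sprintf("segments_rep%d.bed", i)))
        ss
    })
    retained <- if (length(segsets) >= 2L) {
        r <- Reduce(function(a, b) retainReproducible(a, b,
                        minRecip = config$minRecip), segsets)
        .logStage(log, "retain", length(r@segments),
                  " reproducible segments")
        r
    } else segsets[[1L]]
    retained <- segmentEfficiency(retained, pooledDf,
                                  endWindow = config$endWindow,
                                  maskThreshold = config$endMaskThreshold)
    for (i in seq_along(profiles))
        writeRFDBedGraph(profiles[[i]],
                         file.path(config$outDir,
                                   sprintf("rfd_rep%d.bedgraph", i)))
    writeRFDBedGraph(pooledProfile,
                     file.path(config$outDir, "rfd_pooled.bedgraph"))
    timing <- NULL
    if (!is.null(config$timingFile)) {
        timing <- computeS50(readTimingProfile(.checkFile(config$timingFile),
                                               binSize = config$binSize))
        retained <- assignTimingClasses(retained, timing)
        .logStage(log, "timing", sum(!is.na(s50(timing))), " bins with S50")
    }
    asTypes <- NULL
    genes <- NULL
    if (!is.null(config$geneBed)) {
        genes <- readGeneAnnotation(.checkFile(config$geneBed),
                                    .checkFile(config$geneExpr),
                                    activeThreshold = config$activeThreshold)
        asTypes <- classifyASTypes(retained, genes, flank = config$flank,
                                   activeThreshold = config$activeThreshold)
        asr <- .asRanges(retained, "AS")
        utils::write.table(
            data.frame(chrom = as.character(seqnames(asr)),
                       start = start(asr) - 1L, end = end(asr),
                       name = paste0("AS_type", asTypes),
                       score = round(mcols(asr)$efficiency, 1),
                       strand = "."),
            file.path(config$outDir, "as_typed.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
        .logStage(log, "context", length(asTypes), " AS typed")
    }
    writeSegments(retained, file.path(config$outDir, "segments.bed"))
    .logStage(log, "done", "outputs in ", config$outDir)
    invisible(list(profiles = profiles, pooledProfile = pooledProfile,
                   counts = counts, pooledCounts = pooledDf,
                   segsets = segsets, retained = retained,
                   timing = timing, genes = genes, asTypes = asTypes))
}

#' Validate the simulator against its analytical properties
#'
#' Runs a simulation and checks: the timing-directionality identity
#' dMRT/dx = RFD/v; zone-efficiency recovery within a binomial confidence
#' band; replicate RFD correlation; and the window-size calibration trends
#' over 5, 10, 15 kb: replicate slope disagreement strictly decreasing, and
#' the replicate-specific AS fraction (pooled over disjoint replicate
#' pairs) dropping steeply from 5 kb and not rising beyond a 0.05 sampling
#' tolerance on the 10-15 kb plateau.
#'
#' @param config A \code{\link{simulationConfig}} (or YAML path).
#' @param outDir Optional directory for a TSV/JSON report.
#' @return data.frame report (property, value, threshold, pass) with
#'   attribute \code{allPass}. With \code{nCells} = 1 the recovery checks
#'   are skipped with a warning.
#' @export
runSimulationValidation <- function(config, outDir = NULL) {
    if (is.character(config)) config <- readSimulationConfig(config)
    truth <- simulateReplication(config)
    rows <- list()
    addRow <- function(property, value, threshold, pass)
        rows[[length(rows) + 1L]] <<- data.frame(property = property,
            value = value, threshold = threshold, pass = pass)
    cons <- mrtRfdConsistency(truth)
    addRow("mrt_rfd_correlation", cons$correlation, "> 0.99",
           cons$correlation > 0.99)
    if (config$nCells < 2L) {
        warning("nCells = 1: recovery checks skipped (insufficient sampling)")
    } else {
        zs <- zoneStats(truth)
        se <- sqrt(zs$firingProbability * (1 - zs$firingProbability) /
                   config$nCells)
        ## scheduled firing is the Bernoulli(firingProbability) draw;
        ## realized firing is additionally reduced by passive replication
        okZone <- abs(zs$nScheduled / config$nCells -
                      zs$firingProbability) <= pmax(3 * se, 2 / config$nCells)
        addRow("zone_efficiency_recovery", mean(okZone), ">= all within 3 SE",
               all(okZone))
        reps <- sampleOkSeqReads(truth)
        if (length(reps) >= 2L) {
            p1 <- computeRFD(reps[[1L]]); p2 <- computeRFD(reps[[2L]])
            rc <- replicateCorrelation(p1, p2)
            addRow("replicate_correlation", rc$correlation, "> 0.9",
                   rc$correlation > 0.9)
            lv <- c(5000, 10000, 15000)
            sda <- slopeDifferenceAnalysis(reps[[1L]], reps[[2L]],
                                           lValues = lv,
                                           xGrid = 0.05)
            addRow("slope_disagreement_decreasing",
                   paste(round(sda$proportion, 3), collapse = ","),
                   "decreasing in l",
                   !is.unsorted(rev(sda$proportion), strictly = FALSE))
            nPairs <- length(reps) %/% 2L
            fracSpecific <- vapply(lv, function(l) {
                asSets <- lapply(reps[seq_len(2L * nPairs)], function(cc) {
                    pr <- computeRFD(cc, windowSize = l)
                    a <- segmentsFromStates(hmmDecode(quantileEncode(
                        deltaRFD(pr))), pr)@segments
                    a[mcols(a)$state == "AS"]
                })
                tot <- 0L; sh <- 0L
                for (k in seq_len(nPairs)) {
                    a1 <- asSets[[2L * k - 1L]]; a2 <- asSets[[2L * k]]
                    sh <- sh + sum(countOverlaps(a1, a2) > 0L) +
                        sum(countOverlaps(a2, a1) > 0L)
                    tot <- tot + length(a1) + length(a2)
                }
                if (tot == 0L) return(NA_real_)
                1 - sh / tot
            }, 0)
            ## the fraction drops steeply from 5 kb and then plateaus;
            ## the plateau comparison allows 0.05 of sampling noise
            addRow("replicate_specific_as_decreasing",
                   paste(round(fracSpecific, 3), collapse = ","),
                   "decreasing in l (plateau tol 0.05)",
                   !anyNA(fracSpecific) &&
                       fracSpecific[1L] > fracSpecific[2L] &&
                       fracSpecific[1L] > fracSpecific[3L] &&
                       fracSpecific[3L] <= fracSpecific[2L] + 0.05)
        }
        tp <- computeS50(simulateRepliSeq(truth))
        rmse <- sqrt(mean((s50(tp) - trueMRT(truth) /
                           sPhaseDuration(truth))^2, na.rm = TRUE))
        addRow("s50_recovery_rmse", rmse, "< 0.05", rmse < 0.05)
    }
    rep <- do.call(rbind, rows)
    attr(rep, "allPass") <- all(rep$pass)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(rep, file.path(outDir, "validation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(rep, file.path(outDir, "validation.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    rep
}
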