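#' RFD increments between adjacent windows
#'
#' Computes the HMM observation track Delta RFD_n = (RFD(n+1) - RFD(n))/2 for
#' every pair of consecutive window positions; the increment is missing
#' wherever either window is masked.
#'
#' @param profile An \linkS4class{RFDProfile} with uniform step.
#' @return A \linkS4class{DeltaRFDTrack} (codes unassigned; see
#'   \code{\link{quantileEncode}}). Chromosomes with a single window yield no
#'   track positions.
#' @export
deltaRFD <- function(profile) {
    gr <- profile@windows
    step <- profile@step
    chs <- character(0); poss <- numeric(0); dels <- numeric(0)
    for (ch in unique(as.character(seqnames(gr)))) {
        g <- gr[seqnames(gr) == ch]
        if (length(g) < 2L) next
        o <- order(start(g)); g <- g[o]
        r <- mcols(g)$rfd
        pos0 <- start(g) - 1L
        adj <- diff(pos0) == step
        d <- (r[-1L] - r[-length(r)]) / 2
        d[!adj] <- NA_real_
        chs <- c(chs, rep(ch, length(d)))
        poss <- c(poss, pos0[-length(pos0)])
        dels <- c(dels, d)
    }
    new("DeltaRFDTrack", chrom = chs, position = poss, delta = dels,
        code = rep(NA_integer_, length(dels)), step = step)
}

#' Construct a DeltaRFDTrack directly
#'
#' Mainly useful for feeding hand-built observation sequences to
#' \code{\link{hmmDecode}}.
#'
#' @param chrom,position,delta,code,step Slot values; \code{code} may be
#'   supplied directly (1..5) to bypass \code{\link{quantileEncode}}.
#' @return A \linkS4class{DeltaRFDTrack}.
#' @export
DeltaRFDTrack <- function(chrom, position, delta = rep(NA_real_,
                          length(position)), code = rep(NA_integer_,
                          length(position)), step = 1000L) {
    new("DeltaRFDTrack", chrom = rep_len(as.character(chrom),
                                         length(position)),
        position = as.numeric(position), delta = as.numeric(delta),
        code = as.integer(code), step = as.integer(step))
}

#' Encode RFD increments into five equal-frequency quantile codes
#'
#' All non-missing increments genome-wide are ranked (stable rank for ties)
#' and split into five equal-frequency classes coded 1..5; these codes are
#' the categorical observations of the segmentation HMM.
#'
#' @param track A \linkS4class{DeltaRFDTrack}.
#' @return The track with codes assigned. If all increments are equal, every
#'   position receives the median code 3 (with a warning); fewer than five
#'   distinct values trigger a degenerate-coding warning.
#' @export
quantileEncode <- function(track) {
    ok <- !is.na(track@delta)
    if (sum(ok) < 5L) stop("need at least 5 non-missing increments")
    d <- track@delta[ok]
    code <- rep(NA_integer_, length(track@delta))
    if (length(unique(d)) == 1L) {
        warning("all increments equal; degenerate coding (all code 3)")
        code[ok] <- 3L
    } else {
        if (length(unique(d)) < 5L)
            warning("fewer than 5 distinct increment values; ",
                    "quantile coding is degenerate")
        rk <- rank(d, ties.method = "first")
        code[ok] <- pmin(5L, (rk - 1L) %/% (length(d) / 5) + 1L)
    }
    initialize(track, code = as.integer(code))
}

#' Default four-state HMM parameters
#'
#' States are Up (ascending RFD, predominant initiation), Flat1, Down
#' (descending, predominant termination) and Flat2; the transition topology
#' enforces the alternation Up -> (Flat1) -> Down -> (Flat2) -> Up with
#' optional flat spacers and permits directly contiguous ascending/descending
#' segments. Self-transitions are 0.99. Emissions over the five quantile
#' codes favour high codes in Up, low codes in Down and the middle code in
#' the flat states; the two flat states share one emission row and differ
#' only by their position in the cycle (flat after initiation vs after
#' termination).
#'
#' @return A list with \code{states}, row-stochastic \code{transition} (4x4)
#'   and \code{emission} (4x5) matrices, and the uniform \code{initial}
#'   distribution.
#' @export
defaultHMMParameters <- function() {
    states <- c("Up", "Flat1", "Down", "Flat2")
    transition <- matrix(0, 4, 4, dimnames = list(states, states))
    transition["Up", ] <- c(0.99, 0.005, 0.005, 0)
    transition["Flat1", ] <- c(0, 0.99, 0.01, 0)
    transition["Down", ] <- c(0.005, 0, 0.99, 0.005)
    transition["Flat2", ] <- c(0.01, 0, 0, 0.99)
    emission <- rbind(Up = c(0.02, 0.05, 0.13, 0.40, 0.40),
                      Flat1 = c(0.10, 0.20, 0.40, 0.20, 0.10),
                      Down = c(0.40, 0.40, 0.13, 0.05, 0.02),
                      Flat2 = c(0.10, 0.20, 0.40, 0.20, 0.10))
    list(states = states, transition = transition, emission = emission,
         initial = rep(0.25, 4))
}

## Log-space Viterbi with categorical emissions; NA observations are
## uninformative (emission probability 1 in every state).
.viterbi <- function(obs, params) {
    S <- length(params$states)
    n <- length(obs)
    logT <- log(params$transition)
    logE <- log(params$emission)
    V <- matrix(-Inf, S, n)
    ptr <- matrix(0L, S, n)
    V[, 1L] <- log(params$initial) +
        (if (is.na(obs[1L])) 0 else logE[, obs[1L]])
    if (n > 1L) for (t in 2:n) {
        et <- if (is.na(obs[t])) numeric(S) else logE[, obs[t]]
        for (s in seq_len(S)) {
            cand <- V[, t - 1L] + logT[, s]
            b <- which.max(cand)
            ptr[s, t] <- b
            V[s, t] <- cand[b] + et[s]
        }
    }
    path <- integer(n)
    path[n] <- which.max(V[, n])
    if (n > 1L) for (t in n:2) path[t - 1L] <- ptr[path[t], t]
    params$states[path]
}

#' Decode the most probable state path of an RFD increment track
#'
#' Runs Viterbi decoding of the four-state HMM over the quantile-coded
#' increments. Missing observations inside a stretch are treated as
#' uninformative; runs of missing observations spanning more than
#' \code{gapMax} bp split the chromosome into independently decoded
#' stretches (those positions receive no state).
#'
#' @param track A quantile-encoded \linkS4class{DeltaRFDTrack}.
#' @param params HMM parameters as from \code{\link{defaultHMMParameters}};
#'   transition rows and emission rows must sum to one.
#' @param gapMax Maximum masked run (bp) bridged within one decoded stretch.
#' @return A data.frame with columns \code{chrom}, \code{position} (0-based
#'   window-center bin start) and \code{state} (\code{NA} in long gaps).
#' @export
hmmDecode <- function(track, params = defaultHMMParameters(),
                      gapMax = 100000) {
    if (any(abs(rowSums(params$transition) - 1) > 1e-8))
        stop("transition rows must sum to 1")
    if (any(abs(rowSums(params$emission) - 1) > 1e-8))
        stop("emission rows must sum to 1")
    n <- length(track@code)
    state <- rep(NA_character_, n)
    for (ch in unique(track@chrom)) {
        idx <- which(track@chrom == ch)
        idx <- idx[order(track@position[idx])]
        code <- track@code[idx]
        ## split at missing runs longer than gapMax
        miss <- is.na(code)
        r <- rle(miss)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        longGap <- r$values & (r$lengths * track@step > gapMax)
        breakAfter <- logical(length(code))
        for (k in which(longGap)) breakAfter[starts[k]:ends[k]] <- TRUE
        grp <- cumsum(c(TRUE, diff(breakAfter) != 0))
        for (g in unique(grp)) {
            sel <- grp == g
            if (breakAfter[which(sel)[1L]]) next      # the gap itself
            state[idx[sel]] <- .viterbi(code[sel], params)
        }
    }
    data.frame(chrom = track@chrom, position = track@position,
               state = state, stringsAsFactors = FALSE)
}
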