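#' @importFrom Biostrings DNAString DNAStringSet BStringSet letterFrequency
#'   matchPattern reverseComplement
NULL

.asCharSeqs <- function(sequences) {
    if (is(sequences, "XStringSet")) {
        s <- as.character(sequences)
    } else if (is(sequences, "XString")) {
        s <- as.character(sequences)
        names(s) <- "seq1"
    } else s <- sequences
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    s
}

#' Nucleotide compositional skew in adjacent windows
#'
#' GC skew S_GC = (G - C)/(G + C), TA skew S_TA = (T - A)/(T + A) and total
#' skew S = S_GC + S_TA, computed over unmasked positions of adjacent
#' windows. Lowercase letters are treated as repeat-masked (soft-masking
#' convention) and N is always excluded; both count towards the masked
#' fraction.
#'
#' @param sequences Named character vector, \code{BStringSet} or
#'   \code{DNAStringSet} (one entry per chromosome; case preserved).
#' @param window Window width in bp (default 1000, adjacent windows; a
#'   trailing partial window is dropped).
#' @param maxMaskedFraction Windows with a larger masked fraction are
#'   unassigned (default 1: only windows with no countable base, or a zero
#'   denominator, are unassigned).
#' @return A \link[GenomicRanges]{GRanges} of windows with metadata columns
#'   \code{sGC}, \code{sTA}, \code{sTotal}, \code{maskedFraction}.
#' @examples
#' gr <- compositionalSkew(c(chrT = strrep("G", 600)), window = 300)
#' mcols(gr)$sGC   # all-G windows: sGC = 1, sTA unassigned
#' @export
compositionalSkew <- function(sequences, window = 1000L,
                              maxMaskedFraction = 1) {
    s <- .asCharSeqs(sequences)
    out <- list()
    for (ch in names(s)) {
        sq <- gsub("[a-z]", "N", s[[ch]])
        n <- nchar(sq)
        nw <- n %/% window
        if (nw == 0L) next
        dna <- DNAString(sq)
        v <- Biostrings::Views(dna,
                               start = seq(1L, by = window, length.out = nw),
                               width = window)
        lf <- letterFrequency(v, c("A", "C", "G", "T"))
        maskedFraction <- unname(1 - rowSums(lf) / window)
        G <- unname(lf[, "G"]); C <- unname(lf[, "C"])
        T <- unname(lf[, "T"]); A <- unname(lf[, "A"])
        gc <- G + C
        ta <- T + A
        sGC <- ifelse(gc > 0, (G - C) / gc, NA_real_)
        sTA <- ifelse(ta > 0, (T - A) / ta, NA_real_)
        drop <- maskedFraction > maxMaskedFraction
        sGC[drop] <- NA_real_; sTA[drop] <- NA_real_
        out[[ch]] <- GRanges(ch,
            IRanges(start = seq(1L, by = window, length.out = nw),
                    width = window),
            sGC = sGC, sTA = sTA, sTotal = sGC + sTA,
            maskedFraction = maskedFraction)
    }
    if (length(out) == 0L) return(GRanges())
    unname(do.call(c, unname(out)))
}

## All start positions of runs of `GGG` (or `CCC`) in one sequence.
.tripletStarts <- function(dna, letter) {
    start(matchPattern(strrep(letter, 3L), dna))
}

## Exact enumeration of motif spans: four triplet tracks separated by three
## spacers, each spacer length chosen independently in [spacerMin, spacerMax];
## spans containing N are discarded; overlapping spans are merged.
.g4OneStrand <- function(dna, letter, spacerMin, spacerMax) {
    n <- length(dna)
    starts3 <- .tripletStarts(dna, letter)
    if (length(starts3) == 0L) return(IRanges())
    is3 <- logical(n)
    is3[starts3] <- TRUE
    hasN <- cumsum(as.integer(strsplit(as.character(dna), "")[[1]] == "N"))
    res <- list()
    for (s1 in spacerMin:spacerMax) for (s2 in spacerMin:spacerMax)
        for (s3 in spacerMin:spacerMax) {
            len <- 12L + s1 + s2 + s3
            i <- starts3[starts3 + len - 1L <= n]
            if (length(i) == 0L) next
            ok <- is3[i + 3L + s1] & is3[i + 6L + s1 + s2] &
                is3[i + 9L + s1 + s2 + s3]
            i <- i[ok]
            if (length(i) == 0L) next
            nN <- hasN[i + len - 1L] - c(0L, hasN)[i]
            i <- i[nN == 0L]
            if (length(i)) res[[length(res) + 1L]] <-
                IRanges(start = i, width = len)
        }
    if (length(res) == 0L) return(IRanges())
    reduce(do.call(c, res))
}

#' Scan for G-quadruplex-forming motifs
#'
#' Reports maximal genomic intervals matching four tracks of GGG (+ strand)
#' or CCC (- strand) separated by three spacers whose lengths lie
#' independently within [\code{spacerMin}, \code{spacerMax}] nt (defaults 2
#' and 4). Overlapping matches are merged per strand; spans containing N are
#' not reported.
#'
#' @param sequences As in \code{\link{compositionalSkew}} (sequence is
#'   uppercased before scanning).
#' @param spacerMin,spacerMax Spacer length bounds (nt).
#' @return A \link[GenomicRanges]{GRanges} of merged motif hits with strand.
#' @examples
#' g4Scan(c(chrT = "AAGGGTTGGGTTGGGTTGGGAA"))
#' @export
g4Scan <- function(sequences, spacerMin = 2L, spacerMax = 4L) {
    s <- .asCharSeqs(sequences)
    out <- list()
    for (ch in names(s)) {
        dna <- DNAString(toupper(s[[ch]]))
        rp <- .g4OneStrand(dna, "G", spacerMin, spacerMax)
        rm <- .g4OneStrand(dna, "C", spacerMin, spacerMax)
        pieces <- list()
        if (length(rp)) pieces <- c(pieces, GRanges(ch, rp, strand = "+"))
        if (length(rm)) pieces <- c(pieces, GRanges(ch, rm, strand = "-"))
        if (length(pieces))
            out[[length(out) + 1L]] <- sort(do.call(c, pieces),
                                            ignore.strand = TRUE)
    }
    if (length(out) == 0L) return(GRanges())
    unname(do.call(c, out))
}
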