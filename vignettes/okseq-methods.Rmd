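---
title: "Replication fork directionality analysis with okseqr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication fork directionality analysis with okseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(okseqr))
suppressMessages(library(GenomicRanges))
```

## The measurement and its statistic

DNA replication proceeds from origins by two diverging forks. On the
lagging strand of each fork, DNA is made discontinuously as Okazaki
fragments, so a sequenced Okazaki fragment reports the direction of the
fork that produced it: rightward-moving forks deposit fragments on the
Crick strand, leftward-moving forks on the Watson strand. Counting mapped
fragments per strand in genomic windows gives the replication fork
directionality

$$\mathrm{RFD} = \frac{C - W}{C + W},$$

which runs from $-1$ (all forks leftward) through $0$ (balanced) to $+1$
(all forks rightward). Because the two strands are sequenced from the same
DNA, the ratio internally normalizes copy-number and depth variation.
Along a chromosome, zones of predominant initiation appear as ascending
RFD segments (AS), zones of predominant termination as descending segments
(DS), and stretches replicated almost always in one direction as flat
segments (FS) of high |RFD|.

`binStrandedReads()` assigns each read's 5' end to a 1-kb bin (`+` strand
to Watson, `-` to Crick; `flipStrands` inverts the dialect for libraries
with opposite chemistry). `computeRFD()` sums counts in sliding windows
(default 15 kb, stepped 1 kb) and masks any window with fewer than 30
reads on either strand; masked windows carry `NA`, never a numeric zero,
so downstream code cannot mistake missing data for balanced forks.

## Segmentation

The segmentation operates on window-to-window increments
$\Delta\mathrm{RFD}_n = (\mathrm{RFD}_{n+1} - \mathrm{RFD}_n)/2$, encoded
genome-wide into five equal-frequency quantile codes
(`deltaRFD()`, `quantileEncode()`). Equal-frequency coding makes the
observation alphabet scale-free: the decoder sees ranks, not raw
magnitudes, so a single parameter set serves data of any depth.

A four-state hidden Markov model (`Up`, `Flat1`, `Down`, `Flat2`) is
decoded by the Viterbi algorithm (`hmmDecode()`). The transition topology
enforces the biological alternation initiation → (unidirectional) →
termination → (unidirectional) → initiation while permitting directly
contiguous AS/DS, which is common in gene-rich early-replicating regions.
Defaults (all configurable through `defaultHMMParameters()`):
self-transitions 0.99; `Up` emits codes 1..5 with probabilities
(0.02, 0.05, 0.13, 0.40, 0.40), `Down` the mirror image, both flat states
(0.10, 0.20, 0.40, 0.20, 0.10); uniform initial distribution. Missing
observations are treated as uninformative (unit emission); masked runs
longer than `gapMax` (100 kb) split a chromosome into independently
decoded stretches. Decoding is exactly symmetric under profile negation
with `Up`/`Down` and `Flat1`/`Flat2` exchanged, and the test suite checks
the Viterbi path against exhaustive enumeration of all $4^n$ paths on
short tracks.

`segmentsFromStates()` converts maximal state runs to half-open genomic
segments (the two flat states merge to FS). For an AS, the initiation
efficiency is estimated as half the RFD shift across it, in percent:

$$\mathrm{eff} = 100 \times \frac{\mathrm{RFD}_{\mathrm{end}} -
\mathrm{RFD}_{\mathrm{start}}}{2},$$

with the end RFDs measured in 5-kb windows centred on the segment
extremities and clipped to [0, 100]. Under the zone model (at most one
initiation per zone per cell) this equals the fraction of cells in which
the zone fires. The 5-kb end windows default to masking only when empty:
the 30-read-per-strand rule is a property of the 15-kb segmentation
windows, and applying it to 5-kb windows would discard precisely the
high-efficiency zones whose flanks approach |RFD| = 1. FS segments carry
their mean |RFD|, with mean |RFD| > 0.6 flagging strongly unidirectional
replication.

`retainReproducible()` keeps segments found in both biological replicates
with the same state and reciprocal overlap at least 0.5 (configurable),
using the intersection as the retained coordinates; the union alternative
was considered and rejected because intersections cannot overlap each
other after retention.

## Replication timing

Six-fraction Repli-seq assigns each bin an enrichment per S-phase
compartment. `computeS50()` normalizes the six values to sum one, treats
mass as uniform within each sixth of S phase, and interpolates the
abscissa at which the cumulative curve reaches one half. S50 is invariant
under positive rescaling and increases when mass moves later. Real
six-fraction data are conventionally smoothed in 100-kb sliding windows
before interpolation; `smoothWindow` exposes this and defaults to 0
(off) because the packaged simulations are noise-free at the bin level
and smoothing would only blur zone edges. `timingClass()` maps S50 to S1
(0.1, 0.3], S2 (0.3, 0.5], S3 (0.5, 0.7], S4 (0.7, 0.9]; values outside
(0.1, 0.9] are unassigned rather than forced into a class.

At constant fork speed $v$ the mean replication timing (MRT) obeys
$d\mathrm{MRT}/dx = \mathrm{RFD}/v$. `mrtRfdConsistency()` checks the
centred finite difference of MRT against RFD/$v$; on simulations the two
agree almost exactly because each cell's timing curve is piecewise linear
with slope $\pm 1/v$, so the identity fails only at bins containing an
initiation or termination cusp.

## The stochastic replication simulator

`simulateReplication()` implements the replication program that the
analysis assumes, so the whole pipeline can be validated against known
truth:

* **Zones.** Each configured zone fires in a cell with probability
  `firingProbability`, at most once, at a uniformly random position
  within the zone, at a time drawn from a normal distribution truncated
  at zero (the truncation point, not resampling into negative S phase).
* **Background.** Dispersed origins fire as an inhomogeneous Poisson
  process with rate `backgroundRate0` · exp(`backgroundGrowth` · t) per
  kb per minute on unreplicated DNA. Candidates are drawn on the whole
  genome and thinned by passive replication, which is equivalent to
  restricting the process to unreplicated DNA. Because replication time
  is the lower envelope $T(x) = \min_i (t_i + |x - x_i|/v)$ and a
  candidate that is passively replicated before it fires can never win
  anywhere (the envelope is 1/$v$-Lipschitz), the envelope over all
  candidates equals the envelope over realized events; the code exploits
  this and only labels which candidates were realized.
* **Forks.** Constant speed $v$ (default 1.5 kb/min, a typical human
  fork speed), bidirectional, terminating instantly where converging
  forks meet. Every bin of every cell is replicated exactly once.
* **Cells.** A cell with no initiation event is rejected and resampled
  (counted in `nResampled`); with a zero background rate and no firing
  zone this is reported as an error after 100 attempts.

The exponential growth of the background rate is a free parameter of the
cascade picture (later-firing origins towards domain centres), not a
quantity the underlying data constrain; the default (0.01/min) reproduces
the qualitative N-shaped RFD gradient between distant efficient zones.

Ground truth (`ReplicationTruth`) records per-bin true RFD and MRT, the
realized initiation events of every cell, per-zone scheduled and realized
firing counts, and the S-phase duration. Scheduled firing follows the
configured Bernoulli probability exactly; realized firing is additionally
reduced by passive replication from nearby earlier events, which is a
feature of the model, not an estimation error — efficiency estimates are
therefore validated against *realized* zone efficiency.

`sampleOkSeqReads()` draws, per replicate, per-bin Poisson counts with
Crick mean proportional to the fraction of cells replicating the bin
rightward (`readDepth` expected reads per kb). The brief nucleotide-pulse
chemistry of the real protocol is not modelled: asynchronous populations
sample all replicated DNA uniformly, and the analysis consumes only
population-averaged strand fractions. Replicates are independent Poisson
draws from identical truth (replicate r uses `seed + r`); biological
replicate-to-replicate variability is deliberately out of scope — the
replicates exist to exercise concordance and retention logic.
`simulateRepliSeq()` splits S phase into six equal compartments and
returns the per-bin distribution of replication times across cells.

What the simulator does *not* emulate about real data: mappability gaps,
copy-number variation, GC bias, sequence-dependent fragment recovery, and
transcription–replication interactions. Tests passing on these
simulations therefore validate the statistical machinery (formulas,
decoding, retention, recovery) under the stated model, not robustness to
every artefact of real sequencing data — the RFD ratio removes uniform
multiplicative biases by construction, but locus-specific strand biases
would propagate.

## Gene context, nulls and auxiliary tracks

`generateGeneAnnotation()` plants active and inactive genes at controlled
distances and orientations around zones, recording the intended class of
each zone, so the typing logic is testable against construction.
`classifyASTypes()` labels each AS: type 1 when it is flanked by active
genes (at least two within 20 kb) and more than half of it lies in a
non-transcribed interval bounded by active genes; type 2 with exactly one
active gene within the flank; type 3 with none; type 4 otherwise. The
flank-gating of type 1 keeps a zone with no gene anywhere near it from
being classified by genes megabases away. The active/inactive cutoff is
expression > 0 by default and configurable. Genes wholly contained in a
same-strand gene are removed first (`cleanGeneAnnotation()`).

`shuffleNull()` builds the timing-stratified neutral model: genomic
regions of one timing class are concatenated into a virtual chromosome,
on which ascending segments and the gaps separating them are permuted
independently while preserving their alternation and the leading/trailing
gaps; 1,000 shuffles by default. Zone count and length multisets are
conserved exactly in every iteration (asserted at run time). Timing
classes with fewer than two zones cannot be permuted and are passed
through, flagged.

`compositionalSkew()` computes $S_{GC} = (G-C)/(G+C)$,
$S_{TA} = (T-A)/(T+A)$ and their sum in 1-kb adjacent windows, counting
only unmasked uppercase bases (lowercase = repeat-masked, N excluded);
zero denominators leave the component unassigned. `g4Scan()` enumerates
G-quadruplex motifs — four GGG (or CCC) tracks separated by three spacers
of 2–4 nt, each spacer length independent — by explicit enumeration of
the 27 spacer combinations rather than a greedy regular expression, which
makes hit sets exactly mirror-symmetric under reverse complement; spans
containing N are discarded and overlapping hits merged per strand.

`directionalityIndex()` uses the reconstructed form
$\mathrm{DI} = \mathrm{sign}(B-A)\,[(A-E)^2 + (B-E)^2]/E$ with
$E = (A+B)/2$, the sign convention putting large positive DI at domain
left borders. `featureEnrichment()` normalizes feature densities around
anchor borders (or along rescaled anchors) by the mean density of the
examined region, so a uniform feature set gives a flat profile at 1.

## Problem sizes and numerical choices

The packaged simulations are sized for a desk-scale validation rather
than a genome: recovery runs use a 10-Mb chromosome with 20 zones of
efficiency 20–100% at 200 reads/kb and 400 cells, where at least 80% of
zones are recovered with reciprocal overlap ≥ 0.5 and efficiencies land
within ±10 percentage points of realized truth; timing recovery uses
1,000 cells (S50 RMSE < 0.05 against MRT/T_S); the timing-derivative
identity is checked at 1,000 cells (correlation > 0.99).

The window-calibration experiment emulates the coverage regime typical
of OK-seq experiments — a few tens of reads per kb per replicate, the
regime in which 5-kb windows are noise-dominated — with 32 zones of
30 kb and efficiencies 35–65% on 10 Mb over a weak dispersed background.
In that regime the proportion of positions with slope disagreement
> 0.05 falls from roughly half at 5 kb to a few percent at 15 kb, and
the fraction of ascending segments found in only one replicate falls
steeply from 5 kb and plateaus near 20% — which is why 15 kb is the
default segmentation window: it is the point where further smoothing
buys little extra reproducibility but keeps costing spatial resolution.
The replicate-specific fraction is pooled over three
disjoint replicate pairs because a single pair yields only ~100 segments
and its sampling noise (~0.05) is comparable to the 10→15-kb decrement;
`runSimulationValidation()` allows that much tolerance on the plateau
while requiring the steep 5-kb drop strictly.

Other numerical conventions: all text interfaces are 0-based half-open
(BED/bedGraph) with RFD printed to 4 decimals; internal `GRanges` are
1-based closed; windows are emitted only where the full window fits on
the chromosome; quantile ties are broken by stable rank, and a fully
degenerate increment distribution codes to the median bin with a
warning; Viterbi ties resolve to the first state in (`Up`, `Flat1`,
`Down`, `Flat2`) order; `shuffleSegments()` permutes internal gaps only,
so the analysed span is preserved exactly.

## Known limitations

* The HMM transition/emission defaults are package choices exposed as
  parameters; they enforce alternation strongly (self-transition 0.99),
  which suppresses sub-10-kb segments and favours conservative detection
  at small window sizes.
* Efficiency estimates inherit a small negative bias (a few percentage
  points) for very efficient zones because the 5-kb end windows sit
  partially in the smoothed transition ramp; the bias is well inside the
  ±10-point validation band.
* The shuffle null assumes ascending segments do not span timing-region
  boundaries; segments that do are clipped to their majority region.
* `rescaledDomainProfile()` interpolates linearly and extrapolates flat
  at domain edges (`rule = 2`), which slightly dampens extrema for
  domains much shorter than the window size.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(5e6,
    zones = makeZones(5e6, 10, firingProbability = seq(0.3, 1, length.out = 10)),
    nCells = 400, readDepth = 100, seed = 1)
truth <- simulateReplication(cfg)
reps <- sampleOkSeqReads(truth)

profile <- computeRFD(reps[[1]])
track <- quantileEncode(deltaRFD(profile))
segs <- segmentsFromStates(hmmDecode(track), profile, counts = reps[[1]])
segs

timing <- computeS50(simulateRepliSeq(truth))
assignTimingClasses(segs, timing)
```
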