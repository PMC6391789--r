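---
title: "Bias-corrected ATAC-seq footprinting: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected ATAC-seq footprinting: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The README shows the workflow; here we walk
through the model layer by layer, flag every numerically consequential
choice, and state what the synthetic test surface does and does not
establish about real data.

## 1. From read pairs to cleavage signals

A properly paired fragment is reconstructed from the leftmost mate
(`TLEN > 0`) and contributes exactly two cleavage events, one per end. In
ATAC-seq the transposase inserts as a dimer and the centre of the cleavage
event sits at the fifth base of the read, so the forward-read event is
placed at `start + 4` and the reverse-read event at `end - 5`; DNase-seq
uses the 5' position unchanged. The shift pair is configuration
(`shift = c(4L, -5L)`) because the convention for the reverse mate is the
one place different pipelines disagree. Events shifted off-chromosome are
dropped and counted.

Internally every coordinate is 1-based and inclusive — the
GenomicRanges/Biostrings convention — and conversion to BED's 0-based
half-open scheme happens only in the writers. Keeping the container
library's native convention removes an entire class of off-by-one bugs at
the cost of a fixed `-1` in `write_bed6()`.

Fragment-length classes follow the nucleosome ladder: `Nfr = (0, 145]`,
`1N = (145, 307]`, `+1N = (145, Inf]`, `+2N = (307, Inf]`. The defaults
are the standard-protocol boundaries; `estimate_boundaries()` instead
smooths the library's length histogram (moving average, 11 bp window — wide
enough to kill counting noise, narrower than the ~90 bp separation of the
modes) and takes the minima between the first three modes, falling back to
the defaults with a warning when fewer than three modes clear 5% of the
histogram maximum. The minima-between-modes rule is deterministic given
the histogram, which is what the exhaustive-scan tests exploit.

## 2. Cleavage bias

The enzyme's sequence preference for the k-word around a cut,
`b(w) = p(w|obs) / p(w|exp)`, is estimated from the word multiset at cut
sites inside peaks against the multiset over all peak positions (the whole
genome for naked-DNA libraries). Words are extracted on the forward strand
as `G[i - floor(k/2), i + ceiling(k/2) - 1]` and reverse-complemented for
minus-strand events — the enzyme sees the opposite strand there, and the
palindromic structure of the Tn5 motif is only reproduced under this
convention. Words overlapping a chromosome end or containing non-ACGT are
skipped, never fatal.

Three estimators share this interface:

* **k-mer**: multinomial word frequencies. Default `k = 8` for ATAC
  (`k = 6` is the DNase literature's habit); at `k = 8` that is 65,536
  parameters per multiset, which is exactly why the estimator degrades at
  realistic depths.
* **PWM**: independent per-position base frequencies — 4k parameters,
  too rigid for a dimeric enzyme.
* **SLIM**: each position mixes an independent marginal with pairwise
  conditionals on up to `d = 5` upstream positions. Marginals and
  conditionals are frequency estimates; the mixture priors `p(C_j)`,
  `p(R_lj)` are fitted by maximizing the logistic class posterior of
  corpus words against an equal number of uniformly random words (BFGS on
  logit/softmax-transformed priors, analytic gradients, tolerance 1e-6,
  500 iterations, seeded negative draw). Position 1 has no admissible
  parent and its conditional prior is pinned to zero. Forcing
  `p(C_j = 0) = 1` reproduces the PWM bit for bit, and the tests hold the
  package to that identity.

Every estimator adds a pseudocount of 1 — per word (k-mer), per base and
position (PWM), per conditional cell (SLIM) — before normalizing. This is
a regularization choice, not a likelihood-derived one; it exists so that
an unseen 8-mer cannot produce a zero or infinite bias ratio. The
hand-arithmetic tests that verify the printed estimator formulas therefore
set `pseudocount = 0`.

### The correction formula

The corrected signal is `x_i = (y_i + 1) / (yhat_i * bhat(w[i]) + 1)`,
where `bhat` is the bias at `i` divided by the summed bias over the 50 bp
window `[i - 25, i + 24]`. For `yhat` the package defaults to the
**windowed total**, making `yhat * bhat` the expected number of cuts at
`i` under the bias model — a quantity on the same scale as `y_i`. The
alternative reading, `yhat` = windowed *mean*, is implemented as
`expected_counts_mode = "mean"`; at typical depths it makes
`yhat * bhat` two orders of magnitude smaller than 1, the `+1`
regularizer dominates, and the "corrected" track is essentially the raw
track plus one. We verified this on libraries with a planted 20-fold
motif-word preference: in mean mode the planted dips stayed invisible
after correction, in sum mode they surfaced. Both modes are tested against
brute-force evaluation of the formula; only the default is scientifically
live. The correction is scale-free in `b` (window normalization cancels
any constant), truncated windows renormalize over the available
positions, and an all-zero track maps to exactly 1.

## 3. Observation assembly

Per fragment class and strand the pipeline is fixed: bias-correct, then
within-signal normalization (divide by the mean of the *non-zero* values
in an enclosing bin, default 10 kb — bins without signal pass through),
then a logistic squash `1/(1 + e^{-v})` into (0, 1) for the `norm`
channel. The slope channel is a Savitzky–Golay first derivative (order 2,
window 9) of the **pre-logistic** normalized signal: the squash compresses
exactly the dynamic range the slope is supposed to report, so
differentiating after it would discard magnitude information. Bin size,
logistic (unit scale, no shift) and window are config-exposed; none is
printed in the sources this design follows, so they are chosen as sane
defaults and held fixed everywhere, including all tests.

Decomposition strategies are `All`, `Nfr`, `Nfr&+1N`, `Nfr&1N&+2N`, each
with or without strand separation; dimension is `2 × classes × strands`,
between 2 and 12. Channel order is generated deterministically from the
strategy declaration — decode reproducibility depends on it and a test
pins the exact column names.

## 4. The footprint HMM

A fully connected S-state HMM with full-covariance Gaussian emissions.
Training windows are motif centre ± 500 bp for every motif-predicted
binding site supported by a ChIP-seq peak, with the motif interval
labeled FOOTPRINT. Training is semi-supervised:

* the FOOTPRINT emission is estimated once from the labeled positions and
  held fixed;
* during every E-step, labeled positions are clamped to the FOOTPRINT
  state (their emission vector is masked to that state), which conditions
  the forward–backward pass rather than post-hoc overwriting posteriors;
* transitions, the initial distribution, and the other `S - 1` emissions
  are re-estimated by Baum–Welch. Transitions touching the FOOTPRINT
  state stay free — the labels already constrain them through the clamped
  E-step, and fixing them as well would leave the model unable to adapt
  its footprint dwell time.

Initialization deserves a note. The textbook prescription — an M-step
over random posteriors — has a degenerate consequence at this data size:
i.i.d. random responsibilities over thousands of positions average every
unlabeled state's mean to the global data mean, which is an *exact* fixed
point of EM, and training stalls with merged states (we observed two
states with identical means and a flat likelihood after three
iterations). The package therefore takes transitions and the initial
distribution from random posteriors but anchors the unlabeled state means
at k-means centres of the pooled observations (seeded, `nstart = 5`).
This is the same symmetry-breaking that mainstream HMM implementations
use, and with it a 3-state generator is recovered to within 0.03 in means
and transitions from 50 labeled windows.

Numerical choices: scaled (not log-space) forward–backward with
per-position renormalization; covariance ridge `1e-4·I` whenever the
smallest eigenvalue drops below `1e-6`; convergence at relative
log-likelihood change `1e-4` or 100 iterations, returning the best
iterate with a warning otherwise; the training objective is asserted
monotone to `1e-8` relative tolerance in the tests. Viterbi runs in log
space and breaks ties toward the lower state index (`which.max` takes the
first maximum), so decoding is deterministic even for degenerate models.
Runs of the FOOTPRINT state shorter than 5 bp or longer than 50 bp are
discarded — both bounds config-exposed; footprints are scored by the tag
count (summed corrected signal) over their interval for ranking.

The default `S = 9` mirrors the state count a production run would tune
per protocol; the test and acceptance fixtures use `S = 3`–`4`, which is
enough structure for two background states plus footprint at fixture
scale and keeps the suite inside its time budget.

## 5. Motif matching and evaluation

PFMs (JASPAR text) become bit-score PWMs via
`log2(p / background)` with a total pseudocount of 0.8 per column split by
the background composition (uniform 0.25 by default). The score cutoff
for a target FPR is the classical dynamic program over the discretized
null score distribution; the user-facing step is 0.01 bits, and the
matrix is discretized at `step / width` internally so the accumulated
rounding error stays under one step. The DP is validated against
exhaustive enumeration of all `4^len` words on the same discretized
domain (exact agreement) and calibrated on a random genome: the
double-strand match count lands within three binomial standard deviations
of `2 · p · L`.

ChIP labeling: a motif site is true iff its centre lies within 100 bp
(inclusive) of a summit — centre rather than nearest edge, boundary
inclusive, both stated in the function contract and pinned by tests.
Evaluation uses partial AUC (trapezoidal, tied scores merged into one ROC
vertex, clipped and renormalized at the FPR bound) and partial AUPR
(step-curve precision over recall increments). Unpredicted sites enter
with score 0 and share one tie group; the combined ranking score is
`sum of -ln(r / (N + 1))` over the six measures — natural log, matching
the closed form `6·ln 8 ≈ 12.477` for a method ranked first among seven.

## 6. Differential TF activity

Per footprint-supported site (≥ 1 bp overlap with a footprint in either
condition), the activity contribution is the protection term (half-flank
sums of width `e + 1` minus the footprint sum) plus the openness term
(the ± 100 bp window sum); ACT is the mean over sites, conditions are
normalized by DESeq-style median-of-ratios size factors computed on the
per-TF ACT vectors, and `delta = ACT2/w2 - ACT1/w1`. One algebraic fact is
worth stating plainly: because the openness window contains the footprint,
the footprint sum cancels inside each contribution, so ACT responds to
flank and openness changes, not to footprint depth alone. A condition that
merely deepens footprints without touching surrounding accessibility is
invisible to this score; the differential fixtures therefore model a
binding gain the way it manifests in real chromatin — deeper footprint
*plus* elevated local openness. The test statistic is a Welch t-test over
the size-factor-normalized per-site contributions (the per-site population
makes the test independent of how many sites a TF has), BH-corrected
across TFs, flagged at adjusted p < 0.05 with |log2FC| > 0.5; TFs missing
from the expression table are kept and marked `expression_unfiltered`.

## 7. What the synthetic libraries do and do not show

The generator emulates: i.i.d. genomes at a chosen GC; implanted motif
consensus at bound and unbound positions; fragment lengths from a
three-component Gaussian mixture (means 60/200/400 bp, SDs 20/30/40,
weights 0.6/0.3/0.1 — the nucleosome ladder of standard protocols;
config-exposed); cut placement weighted by a planted bias table at both
fragment ends; protection as multiplicative cut suppression inside
footprints; ChIP summits at site centres with Gaussian jitter. The planted
bias table itself has the structure real cleavage motifs have — additive
per-position effects plus weaker adjacent-pair interactions on the log
scale — because an i.i.d.-per-word table contains no positional signal
that any estimator of this family (k-mer included, at realistic depth)
could exploit or that a PDM could represent.

Strand geometry is emergent, not scripted: with full protection, a
nucleosome-free fragment spanning a footprint necessarily cuts left of
the site on the forward end and right of it on the reverse end, and the
tests check the geometry rather than a hard-coded rule.

Not emulated: PCR duplication, mappability, chrM contamination, GC
content of accessibility itself, nucleosome positioning beyond the length
mixture, and TF-specific footprint shapes. Passing tests therefore
establish correctness of the computations and recoverability under the
stated generative model — not calling performance on real libraries.

Two identifiability limits surfaced during fixture design and are worth
knowing about. First, a bias estimator can only learn the enzyme's
preference for motif-like words from *unbound* motif occurrences; in a
fixture where the motif exists only at protected sites, the estimator
attributes the depletion to preference and the correction is a no-op
(real genomes are on the safe side of this — most motif matches are
unbound). Second, if the enzyme *avoids* the motif (planted bias near
zero inside it), protection has nothing left to suppress and the
footprint is genuinely undetectable by any cut-based method; fixture bias
tables use `sd = 0.5` on the log scale to stay clear of that regime, and
the confounded fixture pins the motif-word bias at exactly 20 so that the
residual in-site cut rate `(1 - 0.95) × 20` matches the background at
every seed.

## 8. Problem sizes

Test and acceptance runs use 100 kb genomes with 60,000 fragments for
end-to-end recovery, 30 kb / 9,000 fragments for the file-based command
round trips, 4,000–12,000-word corpora for SLIM, 50 windows × 120
positions for HMM recovery, and 200 kb for motif-count calibration. These
sizes were chosen so every stochastic check operates comfortably above
its noise floor while the whole suite stays quick to run; all of them are
parameters, and nothing in the implementation is specific to fixture
scale.
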