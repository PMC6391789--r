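# atacfoot

Transcription-factor (TF) footprinting for ATAC-seq and DNase-seq.
A DNA-bound protein shields its binding site from the cleavage enzyme, so
an open-chromatin peak carries short local depletions of cut events —
footprints. Calling them from ATAC-seq is harder than it sounds: the Tn5
transposase has a wide, palindromic sequence preference that carves dips
and spikes into the cut profile wherever the sequence suits it, and
fragments that span nucleosomes place their cut sites with a strand
asymmetry around bound TFs. `atacfoot` addresses both, for people who have
aligned reads and peaks and want site-level binding evidence: bias-correct
the cleavage signal, decompose it by strand and nucleosome fragment-size
class, and decode footprints with a semi-supervised hidden Markov model.

## The method

**Cleavage signal.** Each properly paired fragment contributes one cut per
end; for ATAC-seq the event is placed at the fifth base of the read
(+4 forward, −5 reverse), giving strand-specific per-base count vectors
y⁺, y⁻, optionally restricted to a fragment-length class — nucleosome-free
Nfr (0,145], mono-nucleosome 1N (145,307], +1N, +2N, with boundaries either
fixed or estimated from the local minima of the library's fragment-size
distribution.

**Sequence bias.** The enzyme's preference for the k-word w centred on the
cut site is b(w) = p(w|obs)/p(w|exp), where the observed multiset collects
words at cut sites inside peaks and the background multiset every peak
position. Three estimators: multinomial k-mer frequencies; a PWM
(independent positions); and a sparse local inhomogeneous mixture (SLIM)
position-dependency model

p(w) = ∏ⱼ [ p(Cⱼ=0)·p(wⱼ) + p(Cⱼ=1)·Σₗ p(Rₗⱼ)·p(wⱼ|wₗ) ],

whose mixture priors are fitted discriminatively against random words.
A PWM is the special case p(Cⱼ=0) = 1. The corrected signal is
xᵢ = (yᵢ+1)/(ŷᵢ·b̂(w[i])+1) with b̂ the window-normalized bias, so that
ŷᵢ·b̂ is the locally expected cut count under the bias model.

**Decoding.** Per fragment class and strand, the corrected track is
within-bin normalized, logistic-squashed, and paired with its
Savitzky–Golay slope, giving a 2–12-channel observation matrix. A fully
connected S-state HMM with full-covariance Gaussian emissions is trained
semi-supervised: one designated FOOTPRINT state is estimated from motif
positions under ChIP-seq peaks and clamped during Baum–Welch; Viterbi runs
of that state (5–50 bp) become footprint calls, ranked by tag count.

**Downstream.** Motif matching at a fixed FPR (dynamic-programming score
threshold, default 10⁻⁴), ChIP-summit labeling (±100 bp), partial AUC/AUPR
evaluation with a combined ranking score, and a differential TF-activity
score ΔACT = ACT₂/ω₂ − ACT₁/ω₁ with median-of-ratios size factors ω,
Welch t-tests over per-site contributions, BH correction and an expression
fold-change filter.

A synthetic-library generator (genomes, planted motifs and footprints,
biased cleavage, nucleosome fragment-size mixture, jittered ChIP summits)
provides ground truth for every claim the test suite makes.

## Worked example

Simulate a library in which the enzyme's preference masks the footprints
— the residual cut rate inside protected sites matches the background —
then call footprints with and without bias correction:

```r
library(atacfoot)
library(GenomicRanges)

L <- 100000
genome <- simulate_genome(L, seed = 11)
motif  <- "ACGTCAGCATGCAGT"
bound  <- seq(6000, 94000, by = 4400)            # 21 protected sites
decoys <- setdiff(seq(4000, 96000, by = 1100), bound)  # unbound sites
genome <- plant_motif(genome, motif, c(bound, decoys))
truth  <- GRanges("chr1", IRanges(bound, width = nchar(motif)))
peaks  <- GRanges("chr1", IRanges(c(2001, 52001), c(50000, 98000)))

bias <- simulate_bias_table(4, sd = 0.5, seed = 12)
bias[unique(substring(motif, 1:12, 4:15))] <- 20  # enzyme loves the motif
lib  <- simulate_library(genome, 60000, peaks, footprints = truth,
                         protection = 0.95, bias = bias, seed = 13)
chip <- resize(simulate_chipseq(truth, jitter_sd = 10, seed = 14),
               200, fix = "center")

cfg <- footprint_config(bias_method = "kmer", k = 4, S = 4, seed = 15,
                        strategy = "All", max_iter = 50)
res <- call_footprints(lib$fragments, peaks, genome, cfg,
                       train_mpbs = truth, train_chip = chip)
res$footprints[1:2]
#> GRanges object with 2 ranges and 2 metadata columns:
#>       seqnames    ranges strand |     score               name
#>   [1]     chr1 3282-3286      * |   6.98222 footprint_All_0001
#>   [2]     chr1 5998-6014      * |  23.14014 footprint_All_0002

recall <- function(calls)
  sum(countOverlaps(truth, calls, minoverlap = 8L) > 0) / length(truth)
recall(res$footprints)
#> [1] 0.9047619

cfg0 <- footprint_config(bias_method = "none", S = 4, seed = 15,
                         strategy = "All", max_iter = 50)
res0 <- call_footprints(lib$fragments, peaks, genome, cfg0,
                        train_mpbs = truth, train_chip = chip)
recall(res0$footprints)
#> [1] 0.7142857

cor(bias_ratio(res$bias_model, names(bias)), bias, method = "spearman")
#> [1] 0.993009
```

The second call (chr1:5998–6014) lands on the first planted site
(6000–6014). With bias correction 19 of 21 planted footprints are
recovered; without it, 15 — the dip only becomes visible once the signal
is divided by the expected cut rate. The estimated k-mer table tracks the
planted enzyme preference at Spearman ρ = 0.99.

A command-line interface wraps the same functions
(`exec/atacfoot footprint|tracks|evaluate|differential`); every command is
byte-reproducible given a seed and writes its configuration next to its
outputs.

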