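# Shared fixture builders. Everything is generated in code, deterministic
# per seed.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

BASES <- c("A", "C", "G", "T")

# deterministic tri-modal fragment-length histogram whose smoothed minima
# sit near 145 and 307 (expected counts of a Gaussian mixture, no sampling)
tri_modal_histogram <- function(n = 1e6) {
  x <- 1:1000
  dens <- 0.62 * dnorm(x, 60, 40) + 0.33 * dnorm(x, 200, 35) +
    0.05 * dnorm(x, 400, 50)
  round(n * dens)
}

# recall of `truth` among `calls` at >= 50% reciprocal overlap
reciprocal_recall <- function(truth, calls) {
  if (length(calls) == 0) return(0)
  ov <- findOverlaps(truth, calls)
  if (length(ov) == 0) return(0)
  w <- width(pintersect(truth[queryHits(ov)], calls[subjectHits(ov)]))
  ok <- w >= 0.5 * width(truth[queryHits(ov)]) &
    w >= 0.5 * width(calls[subjectHits(ov)])
  length(unique(queryHits(ov)[ok])) / length(truth)
}

# planted-footprint fixture: genome with a consensus motif implanted at
# bound (protected) and unbound (decoy) sites, biased cleavage, ChIP truth.
# confounded = TRUE boosts the enzyme's preference for motif words so the
# footprint dip is masked in uncorrected signal.
footprint_fixture <- function(L = 100000L, n_fragments = 60000L,
                              confounded = FALSE, protection = 0.95,
                              bias_sd = 0.5, seed = 11L) {
  genome <- simulate_genome(L, seed = seed)
  motif <- "ACGTCAGCATGCAGT"
  bound <- seq(6000L, L - 6000L, by = 4400L)
  decoys <- setdiff(seq(4000L, L - 4000L, by = 1100L), bound)
  far <- apply(abs(outer(decoys, bound, "-")), 1, min) > 600
  decoys <- decoys[far][seq_len(min(60L, sum(far)))]
  genome <- plant_motif(genome, motif, c(bound, decoys))
  truth <- GRanges("chr1", IRanges(bound, width = nchar(motif)))
  peaks <- GRanges("chr1", IRanges(c(2001L, L %/% 2 + 2001L),
                                   c(L %/% 2, L - 2000L)))
  bias <- simulate_bias_table(4L, sd = bias_sd, seed = seed + 1L)
  if (confounded) {
    # enzyme strongly prefers motif-like words: the residual cut rate
    # inside a protected site, (1 - protection) * 20, matches the
    # background, so the footprint dip is invisible before correction
    mw <- unique(substring(motif, 1:(nchar(motif) - 3L), 4:nchar(motif)))
    bias[mw] <- 20
  }
  lib <- simulate_library(genome, n_fragments, peaks, footprints = truth,
                          protection = protection, bias = bias,
                          seed = seed + 2L)
  summits <- simulate_chipseq(truth, jitter_sd = 10, seed = seed + 3L)
  list(genome = genome, motif = motif, truth = truth, peaks = peaks,
       bias = bias, fragments = lib$fragments, summits = summits,
       chip_peaks = resize(summits, 200L, fix = "center"))
}

# small hand-checkable JASPAR text fixture
jaspar_fixture_path <- function() {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(
    ">MA0001.1 TOYA",
    "A [ 10  0  0  2 ]",
    "C [  0 10  0  2 ]",
    "G [  0  0 10  2 ]",
    "T [  0  0  0  4 ]",
    ">MA0002.1 TOYB",
    "A [ 5 5 ]",
    "C [ 5 0 ]",
    "G [ 0 5 ]",
    "T [ 0 0 ]"), path)
  path
}

# brute-force per-word probability under a PWM bias model's obs matrix
pwm_prob_brute <- function(probs, words) {
  vapply(words, function(w) {
    b <- match(strsplit(w, "")[[1]], BASES)
    prod(probs[cbind(seq_along(b), b)])
  }, numeric(1), USE.NAMES = FALSE)
}

# exact window score of a word under a bit-score PWM
pwm_score_word <- function(pwm, w) {
  b <- match(strsplit(w, "")[[1]], BASES)
  sum(pwm[cbind(b, seq_along(b))])
}

random_words <- function(n, k) {
  apply(matrix(sample(BASES, n * k, replace = TRUE), ncol = k),
        1, paste, collapse = "")
}
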