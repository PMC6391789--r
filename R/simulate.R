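# Synthetic ATAC-seq libraries: genomes, planted motifs and footprints,
# sequence-biased cleavage, and nucleosome fragment-size structure. These
# generators are the package's test surface; they emulate the geometry of
# real libraries (fragment-size modes near 60/200/400 bp, strand-specific
# cut placement around protected sites) but not PCR duplication,
# mappability or chrM artifacts.

#' Simulate an i.i.d. genome sequence
#'
#' @param length Sequence length (>= 1000).
#' @param gc GC content in `[0, 1]`.
#' @param seed Random seed (draw is deterministic per seed).
#' @param chrom Chromosome name.
#' @return A named `DNAStringSet` of length 1.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L, chrom = "chr1") {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  old <- .Random.seed_save()
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(DNA_BASES, length, replace = TRUE, prob = p),
             collapse = "")
  .Random.seed_restore(old)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- chrom
  out
}

#' Plant motif occurrences into a genome
#'
#' Overwrites the sequence with `motif` starting at each given position
#' (forward strand).
#'
#' @param genome `DNAStringSet`.
#' @param motif Character consensus to implant.
#' @param starts 1-based start positions.
#' @return Modified `DNAStringSet`; the implanted intervals are available
#'   as attribute `sites` (`GRanges`).
#' @export
plant_motif <- function(genome, motif, starts) {
  chrom <- names(genome)[1]
  s <- genome_chars(genome, chrom)
  for (p in starts) substr(s, p, p + nchar(motif) - 1L) <- motif
  out <- Biostrings::DNAStringSet(s)
  names(out) <- chrom
  attr(out, "sites") <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, starts + nchar(motif) - 1L))
  out
}

#' Simulate a sequence cleavage-bias table
#'
#' Generates an enzyme preference with the structure real cleavage motifs
#' have: additive per-position base effects plus weaker adjacent-pair
#' interaction effects on the log scale,
#' `log b(w) = sum_j a_j(w_j) + sum_j c_j(w_(j-1), w_j)` (centered).
#' Deterministic per seed.
#'
#' @param k Word length (<= 8 to keep the table enumerable).
#' @param sd Standard deviation of the per-position effects `a_j`.
#' @param pair_sd Standard deviation of the adjacent-pair effects `c_j`
#'   (default `sd / 2`).
#' @param seed Random seed.
#' @return Named numeric vector `b(w)` over all `4^k` words.
#' @export
simulate_bias_table <- function(k, sd = 0.5, seed = 1L, pair_sd = sd / 2) {
  stopifnot(k <= 8)
  words <- all_words(k)
  wm <- word_matrix(words, k)
  old <- .Random.seed_save()
  set.seed(seed)
  a <- matrix(rnorm(k * 4, 0, sd), k, 4)
  logb <- numeric(length(words))
  for (j in seq_len(k)) logb <- logb + a[j, wm[, j]]
  if (k > 1 && pair_sd > 0) {
    for (j in 2:k) {
      cj <- matrix(rnorm(16, 0, pair_sd), 4, 4)
      logb <- logb + cj[cbind(wm[, j - 1L], wm[, j])]
    }
  }
  .Random.seed_restore(old)
  stats::setNames(exp(logb - mean(logb)), words)
}

#' Enumerate all ACGT words of length k
#'
#' @param k Word length.
#' @return Character vector of `4^k` words in lexicographic order.
#' @export
all_words <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k))[seq_len(k)]))
}

#' Simulate a paired-end ATAC-seq library
#'
#' Fragment lengths are drawn from a Gaussian mixture over nucleosome
#' classes; fragment placement inside the accessible peaks is weighted by
#' the planted sequence bias at both cut sites (forward cut at
#' `start + shift[1]`, reverse cut at `end + shift[2]`) and suppressed by
#' the protection depth where a cut would fall inside a planted footprint.
#' Nucleosome-free fragments spanning a footprint therefore show the
#' canonical strand geometry (forward cuts left of the site, reverse cuts
#' right) without further modeling.
#'
#' @param genome `DNAStringSet`.
#' @param n_fragments Number of fragments (> 0).
#' @param peaks `GRanges` of accessible regions fragments are drawn from
#'   (chosen proportionally to width).
#' @param footprints Optional `GRanges` of protein-protected sites.
#' @param protection Fraction of cleavage suppressed inside footprints
#'   (`[0, 1]`; 1 = no cuts inside).
#' @param bias Optional named bias table over all k-words (see
#'   [simulate_bias_table()]); `NULL` for an unbiased enzyme.
#' @param frag_means,frag_sds,frag_weights Fragment-length mixture
#'   (defaults 60/200/400 bp, SD 20/30/40, weights 0.6/0.3/0.1, matching
#'   the nucleosome-free/mono/di modes of real libraries).
#' @param shift Cut-site shift pair (ATAC default `c(4L, -5L)`).
#' @param min_len Minimum fragment length after truncation (default 20).
#' @param seed Random seed.
#' @return `list(fragments, truth)`: a fragment `data.frame`
#'   (`chrom`, `start`, `end`, `length`, `class`) and the footprint truth
#'   `GRanges`.
#' @export
simulate_library <- function(genome, n_fragments, peaks, footprints = NULL,
                             protection = 0.9, bias = NULL,
                             frag_means = c(60, 200, 400),
                             frag_sds = c(20, 30, 40),
                             frag_weights = c(0.6, 0.3, 0.1),
                             shift = c(4L, -5L), min_len = 20L, seed = 1L) {
  stopifnot(n_fragments > 0, length(peaks) > 0,
            abs(sum(frag_weights) - 1) < 1e-9)
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]

  # per-position weights for a fragment to START at p (forward cut at
  # p + shift[1]) or to END at p (reverse cut at p + shift[2])
  wcut_f <- cut_weights(genome, chrom, L, bias, footprints, protection, "+")
  wcut_r <- cut_weights(genome, chrom, L, bias, footprints, protection, "-")
  wstart <- shifted_weight(wcut_f, shift[1])
  wend <- shifted_weight(wcut_r, shift[2])

  old <- .Random.seed_save()
  set.seed(seed)
  comp <- sample.int(length(frag_means), n_fragments, replace = TRUE,
                     prob = frag_weights)
  len <- pmax(min_len, round(rnorm(n_fragments, frag_means[comp],
                                   frag_sds[comp])))
  pk <- sample.int(length(peaks), n_fragments, replace = TRUE,
                   prob = GenomicRanges::width(peaks))
  starts <- integer(n_fragments)
  for (grp in split(seq_len(n_fragments), paste(pk, len))) {
    i1 <- grp[1]
    p <- peaks[pk[i1]]
    lo <- GenomicRanges::start(p)
    hi <- GenomicRanges::end(p) - len[i1] + 1L
    if (hi < lo) { starts[grp] <- NA_integer_; next }
    cand <- lo:hi
    w <- wstart[cand] * wend[cand + len[i1] - 1L]
    if (all(w == 0)) w <- rep(1, length(w))
    starts[grp] <- cand[sample.int(length(cand), length(grp),
                                   replace = TRUE, prob = w)]
  }
  .Random.seed_restore(old)
  keep <- !is.na(starts)
  fr <- data.frame(chrom = chrom, start = starts[keep],
                   end = starts[keep] + len[keep] - 1L,
                   length = len[keep],
                   class = classify_fragment(len[keep]),
                   stringsAsFactors = FALSE)
  list(fragments = fr, truth = footprints)
}

# weight of a cleavage event at each genomic position for one strand
cut_weights <- function(genome, chrom, L, bias, footprints, protection,
                        strand) {
  w <- rep(1, L)
  if (!is.null(bias)) {
    k <- nchar(names(bias)[1])
    words <- extract_word(genome, seq_len(L), k, chrom = chrom,
                          strand = strand)
    ok <- !is.na(words)
    w[ok] <- unname(bias[words[ok]])
  }
  if (!is.null(footprints) && protection > 0) {
    for (i in seq_along(footprints)) {
      idx <- GenomicRanges::start(footprints[i]):GenomicRanges::end(footprints[i])
      w[idx] <- w[idx] * (1 - protection)
    }
  }
  w
}

# weight for the *unshifted* position given the cut lands at pos + s
shifted_weight <- function(wcut, s) {
  L <- length(wcut)
  p <- seq_len(L) + s
  out <- numeric(L)
  ok <- p >= 1L & p <= L
  out[ok] <- wcut[p[ok]]
  out
}

#' Simulate ChIP-seq summits for planted sites
#'
#' One summit per truth footprint at its center plus Gaussian jitter.
#'
#' @param truth `GRanges` of planted footprints.
#' @param jitter_sd Summit jitter SD in bp (0 = exact centers).
#' @param seed Random seed.
#' @return Width-1 `GRanges` of summits.
#' @export
simulate_chipseq <- function(truth, jitter_sd = 0, seed = 1L) {
  if (length(truth) == 0)
    return(GenomicRanges::GRanges())
  centers <- (GenomicRanges::start(truth) + GenomicRanges::end(truth)) %/% 2L
  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    centers <- centers + round(rnorm(length(centers), 0, jitter_sd))
    .Random.seed_restore(old)
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(truth),
                         IRanges::IRanges(centers, centers))
}

#' Write simulated fragments as an indexed BAM file
#'
#' Emits proper read pairs (36 bp mates at the fragment ends, MAPQ 60) in
#' SAM, converts with `Rsamtools::asBam` and indexes the result.
#'
#' @param fragments Fragment `data.frame` (see [simulate_library()]).
#' @param genome `DNAStringSet` (for the header and read sequences).
#' @param path Output BAM path (without or with `.bam` extension).
#' @param read_len Mate read length (clipped to the fragment length).
#' @return The BAM path (index written alongside).
#' @export
write_bam_fragments <- function(fragments, genome, path, read_len = 36L) {
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, L)), con)
  fr <- fragments[order(fragments$start), , drop = FALSE]
  rl <- pmin(read_len, fr$length)
  seq1 <- substring(genome_chars(genome, chrom), fr$start,
                    fr$start + rl - 1L)
  seq2 <- revcomp(substring(genome_chars(genome, chrom),
                            fr$end - rl + 1L, fr$end))
  qual <- vapply(rl, function(n) strrep("I", n), character(1))
  recs <- character(2L * nrow(fr))
  for (i in seq_len(nrow(fr))) {
    qn <- sprintf("frag%06d", i)
    p1 <- fr$start[i]
    p2 <- fr$end[i] - rl[i] + 1L
    cig <- sprintf("%dM", rl[i])
    recs[2L * i - 1L] <- paste(qn, 99, chrom, p1, 60, cig, "=", p2,
                               fr$length[i], seq1[i], qual[i], sep = "\t")
    recs[2L * i] <- paste(qn, 147, chrom, p2, 60, cig, "=", p1,
                          -fr$length[i], seq2[i], qual[i], sep = "\t")
  }
  writeLines(recs, con)
  close(con)
  path <- sub("\\.bam$", "", path)
  raw <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  bam <- Rsamtools::sortBam(raw, path)
  Rsamtools::indexBam(bam)
  unlink(c(sam, raw))
  bam
}

#' Write a genome FASTA with index
#'
#' @param genome `DNAStringSet`.
#' @param path Output FASTA path.
#' @return The path (with `.fai` index alongside).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  Rsamtools::indexFa(path)
  path
}
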