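# Motif matching at a fixed false-positive rate.
#
# Position frequency matrices (JASPAR text format) are converted to
# log2-odds PWMs; the bit-score cutoff for a target FPR is found by dynamic
# programming over the discretized score distribution under the background
# model, and both strands are scanned.

#' Read motifs from a JASPAR PFM flat file
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four rows
#' `A [ counts ]` ... `T [ counts ]` (brackets optional).
#'
#' @param path Path to the PFM file.
#' @return Named list of `4 x width` count matrices (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  stopifnot(length(heads) > 0)
  out <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]]
    name <- name[length(name)]
    rows <- lines[(heads[i] + 1L):(heads[i] + 4L)]
    mat <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGT]\\s*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGT]\\s*\\[?|\\]\\s*$", "",
                                           rows[1])), "\\s+")[[1]]))))
    rownames(mat) <- DNA_BASES
    out[[name]] <- mat
  }
  out
}

#' Convert a position frequency matrix to a bit-score PWM
#'
#' Per cell: `log2(p / background)` with
#' `p = (count + pseudocount * background) / (N + pseudocount)`, i.e. the
#' pseudocount is split by the background composition.
#'
#' @param pfm `4 x width` count matrix (rows A, C, G, T).
#' @param background Length-4 base probabilities (default uniform).
#' @param pseudocount Total pseudocount per column (default 0.8).
#' @return `4 x width` log2-odds matrix (bits).
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(nrow(pfm) == 4L, all(pfm >= 0), abs(sum(background) - 1) < 1e-9)
  nc <- colSums(pfm)
  if (any(nc == 0)) stop("PFM column with zero total count")
  p <- sweep(pfm + pseudocount * background, 2, nc + pseudocount, "/")
  pwm <- log2(p / background)
  rownames(pwm) <- DNA_BASES
  pwm
}

#' Bit-score cutoff at a target false-positive rate
#'
#' Dynamic programming over the discretized score distribution: scores are
#' rounded to a fixed step, the exact distribution of the window score under
#' the background model is built by convolution across motif positions, and
#' the smallest cutoff `t` with `P(score >= t) <= fpr` is returned.
#'
#' @param pwm Bit-score matrix (see [pfm_to_pwm()]).
#' @param background Length-4 base probabilities of the null model.
#' @param fpr Target false-positive rate per strand and position.
#' @param step Score discretization step in bits (default 0.01). The
#'   matrix is discretized at `step / ncol(pwm)` internally so the summed
#'   rounding error stays below one step.
#' @return Cutoff in bits, with attribute `achieved_fpr` (the discretized
#'   null exceedance probability at the cutoff).
#' @export
threshold_at_fpr <- function(pwm, background = rep(0.25, 4), fpr = 1e-4,
                             step = 0.01) {
  stopifnot(fpr > 0, fpr <= 1, ncol(pwm) <= 30)
  step <- step / ncol(pwm)
  q <- round(pwm / step)  # integer scores
  dist <- 1  # probability vector over shifted integer scores, index 1 = min
  for (j in seq_len(ncol(pwm))) {
    qj <- q[, j] - min(q[, j])
    newlen <- length(dist) + max(qj)
    nd <- numeric(newlen)
    for (b in 1:4) {
      idx <- seq_along(dist) + qj[b]
      nd[idx] <- nd[idx] + dist * background[b]
    }
    dist <- nd
  }
  minscore <- sum(apply(q, 2, min))
  tailp <- rev(cumsum(rev(dist)))
  ok <- which(tailp <= fpr)
  idx <- if (length(ok) == 0) length(dist) else min(ok)
  cutoff <- (minscore + idx - 1L) * step
  attr(cutoff, "achieved_fpr") <- tailp[idx]
  cutoff
}

# score every window start of an integer-coded sequence; NA where the window
# contains a non-ACGT base
score_windows <- function(seqint, pwm) {
  k <- ncol(pwm)
  n <- length(seqint) - k + 1L
  if (n < 1L) return(numeric(0))
  sc <- rep(0, n)
  for (j in seq_len(k)) {
    sc <- sc + pwm[, j][seqint[seq_len(n) + j - 1L]]
  }
  sc
}

#' Scan sequences for motif-predicted binding sites
#'
#' Scores every window on both strands and reports those at or above the
#' cutoff.
#'
#' @param genome `DNAStringSet` (or single character string named via
#'   `chrom`).
#' @param pwm Bit-score matrix.
#' @param cutoff Bit-score cutoff (see [threshold_at_fpr()]).
#' @param chrom Chromosome name when `genome` is a bare string.
#' @param motif_name Name stored in the result.
#' @return `GRanges` of MPBS with metadata columns `score`, `motif`; strand
#'   set per match orientation.
#' @export
scan_motif <- function(genome, pwm, cutoff, chrom = NULL,
                       motif_name = "motif") {
  chroms <- if (is.character(genome)) {
    stats::setNames(list(genome), chrom %||% "seq")
  } else {
    stats::setNames(lapply(names(genome), function(ch) genome_chars(genome, ch)),
                    names(genome))
  }
  k <- ncol(pwm)
  res <- list()
  for (ch in names(chroms)) {
    s <- chroms[[ch]]
    seqint <- match(strsplit(s, "")[[1]], DNA_BASES)
    fwd <- score_windows(seqint, pwm)
    rev_ <- score_windows(seqint, revcomp_pwm(pwm))
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev_
      hit <- which(!is.na(sc) & sc >= cutoff)
      if (length(hit) == 0) next
      res[[length(res) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(hit, hit + k - 1L), strand = str,
        score = sc[hit], motif = motif_name)
    }
  }
  if (length(res) == 0) {
    return(GenomicRanges::GRanges(score = numeric(0), motif = character(0)))
  }
  sort(do.call(c, res), ignore.strand = TRUE)
}

# reverse-complement a PWM: reverse columns, swap complementary base rows
revcomp_pwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label MPBS with ChIP-seq evidence
#'
#' A site is a true binding site iff its center lies within `radius` bp
#' (inclusive) of any ChIP-seq peak summit; otherwise a false site.
#'
#' @param mpbs `GRanges` of motif-predicted binding sites.
#' @param summits `GRanges` (width-1) of ChIP-seq peak summits.
#' @param radius Distance threshold in bp (default 100, inclusive).
#' @return `mpbs` with a logical metadata column `true_site`.
#' @export
label_with_chipseq <- function(mpbs, summits, radius = 100L) {
  centers <- (GenomicRanges::start(mpbs) + GenomicRanges::end(mpbs)) %/% 2L
  cen_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(mpbs),
                                   IRanges::IRanges(centers, centers))
  hits <- GenomicRanges::distanceToNearest(cen_gr, summits,
                                           ignore.strand = TRUE)
  true_site <- rep(FALSE, length(mpbs))
  # distanceToNearest reports gap size; center exactly at distance r from a
  # width-1 summit has gap r - 1
  true_site[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(hits)$distance <= radius - 1L |
    S4Vectors::mcols(hits)$distance == 0L
  S4Vectors::mcols(mpbs)$true_site <- true_site
  mpbs
}
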