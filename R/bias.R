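# Sequence cleavage-bias estimation and signal correction.
#
# The bias of the cleavage enzyme (Tn5 or DNase-I) for a k-word w is
# b(w) = p(w | observed cut sites) / p(w | background), where the word at
# position p is G[p - floor(k/2), p + ceiling(k/2) - 1] (1-based, inclusive).
# Three estimators of p(w) are provided: multinomial k-mer frequencies,
# position weight matrices (independent positions), and SLIM position
# dependency models (see slim.R).

#' Extract the k-word centered at a genomic position
#'
#' @param genome A `DNAStringSet` (named chromosomes) or single character
#'   string.
#' @param pos 1-based position(s) of the cleavage event.
#' @param k Word length.
#' @param chrom Chromosome name (ignored when `genome` is a bare string).
#' @param strand `"+"` or `"-"`; reverse-strand words are
#'   reverse-complemented after extraction from the forward genome.
#' @return Character vector of words; `NA` where the word overhangs the
#'   chromosome or contains a non-ACGT base (such positions are skipped by
#'   the estimators, not fatal).
#' @export
extract_word <- function(genome, pos, k, chrom = NULL, strand = "+") {
  seqchar <- genome_chars(genome, chrom)
  lo <- pos - k %/% 2L
  hi <- pos + (k + 1L) %/% 2L - 1L
  w <- rep(NA_character_, length(pos))
  ok <- lo >= 1L & hi <= nchar(seqchar)
  if (any(ok)) w[ok] <- substring(seqchar, lo[ok], hi[ok])
  w[!grepl("^[ACGT]+$", w)] <- NA_character_
  if (any(strand == "-")) {
    neg <- strand == "-" & !is.na(w)
    w[neg] <- revcomp(w[neg])
  }
  w
}

genome_chars <- function(genome, chrom = NULL) {
  if (is.character(genome)) return(genome)
  if (is.null(chrom)) {
    stopifnot(length(genome) == 1L)
    chrom <- names(genome)[1L]
  }
  as.character(genome[[chrom]])
}

revcomp <- function(w) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(w)))
}

#' Collect observed and background word multisets
#'
#' The observed multiset holds the k-word around every cleavage event inside
#' the peak set, with multiplicity equal to the event count; the background
#' multiset holds the word at every position of every peak (whole-genome
#' background is selected by passing peaks covering the full chromosome, as
#' for naked-DNA libraries).
#'
#' @param tracks List of [cleavage_track()]s (e.g. one per strand) whose
#'   events are to be counted.
#' @param peaks `GRanges` of accessible (peak) regions.
#' @param genome `DNAStringSet`.
#' @param k Word length.
#' @return `list(obs = character, exp = character)` word multisets.
#' @export
collect_words <- function(tracks, peaks, genome, k) {
  obs <- lapply(tracks, function(tr) {
    pos <- which(tr$counts > 0) + tr$region$start - 1L
    cnt <- tr$counts[tr$counts > 0]
    gr <- GenomicRanges::GRanges(tr$region$chrom, IRanges::IRanges(pos, pos))
    inpk <- IRanges::overlapsAny(gr, peaks)
    w <- extract_word(genome, pos[inpk], k, chrom = tr$region$chrom,
                      strand = tr$strand)
    rep(w, cnt[inpk])
  })
  obs <- unlist(obs, use.names = FALSE)
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0L) stop("no observed words inside peaks")
  expw <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    pos <- seq(GenomicRanges::start(p), GenomicRanges::end(p))
    extract_word(genome, pos, k,
                 chrom = as.character(GenomicRanges::seqnames(p)))
  })
  expw <- unlist(expw, use.names = FALSE)
  list(obs = obs, exp = expw[!is.na(expw)])
}

#' k-mer bias table
#'
#' Multinomial estimate of word probabilities in the observed and background
#' multisets; the bias of word `w` is the ratio of the two probabilities.
#' A pseudocount is added to every one of the 4^k word counts (implicitly:
#' unseen words are handled through the adjusted totals).
#'
#' @param w_obs,w_exp Character word multisets (see [collect_words()]).
#' @param k Word length.
#' @param pseudocount Added to every word count before normalization;
#'   default 1. Use 0 for the plain maximum-likelihood estimate.
#' @return An object of class `c("kmer_bias", "bias_model")`.
#' @export
estimate_kmer <- function(w_obs, w_exp, k, pseudocount = 1) {
  stopifnot(length(w_obs) > 0, length(w_exp) > 0)
  structure(list(k = as.integer(k), pseudocount = pseudocount,
                 obs = word_counts(w_obs), exp = word_counts(w_exp),
                 n_obs = length(w_obs), n_exp = length(w_exp)),
            class = c("kmer_bias", "bias_model"))
}

word_counts <- function(w) {
  tb <- table(w)
  stats::setNames(as.numeric(tb), names(tb))
}

kmer_prob <- function(counts, total, words, k, pc) {
  cnt <- counts[words]
  cnt[is.na(cnt)] <- 0
  unname((cnt + pc) / (total + pc * 4^k))
}

#' Position-weight-matrix bias model
#'
#' Assumes independence between word positions: `p(w) = prod_j p(w_j)`,
#' with per-position base probabilities estimated from the multisets
#' (pseudocount added to every base count per position).
#'
#' @inheritParams estimate_kmer
#' @return An object of class `c("pwm_bias", "bias_model")`.
#' @export
estimate_pwm <- function(w_obs, w_exp, pseudocount = 1) {
  stopifnot(length(w_obs) > 0, length(w_exp) > 0)
  k <- unique(nchar(c(w_obs[1], w_exp[1])))
  stopifnot(length(k) == 1L)
  structure(list(k = as.integer(k), pseudocount = pseudocount,
                 obs = position_probs(w_obs, k, pseudocount),
                 exp = position_probs(w_exp, k, pseudocount)),
            class = c("pwm_bias", "bias_model"))
}

# k x 4 matrix of per-position base probabilities
position_probs <- function(words, k, pc) {
  m <- word_matrix(words, k)
  counts <- vapply(seq_len(k), function(j) tabulate(m[, j], nbins = 4L),
                   numeric(4L))
  probs <- t(counts + pc) / (length(words) + 4 * pc)
  colnames(probs) <- DNA_BASES
  probs
}

# words -> n x k integer matrix of base indices (A=1 C=2 G=3 T=4)
word_matrix <- function(words, k) {
  chars <- matrix(match(unlist(strsplit(words, ""), use.names = FALSE),
                        DNA_BASES), ncol = k, byrow = TRUE)
  stopifnot(!anyNA(chars))
  chars
}

pwm_word_prob <- function(probs, words) {
  k <- nrow(probs)
  m <- word_matrix(words, k)
  p <- rep(1, length(words))
  for (j in seq_len(k)) p <- p * probs[j, ][m[, j]]
  unname(p)
}

#' Bias ratio b(w) of a fitted bias model
#'
#' @param model A `bias_model` (from [estimate_kmer()], [estimate_pwm()] or
#'   [fit_slim()]).
#' @param words Character vector of k-words.
#' @return Numeric vector `b(w) = p(w|obs) / p(w|exp)`.
#' @export
bias_ratio <- function(model, words) UseMethod("bias_ratio")

#' @export
bias_ratio.kmer_bias <- function(model, words) {
  kmer_prob(model$obs, model$n_obs, words, model$k, model$pseudocount) /
    kmer_prob(model$exp, model$n_exp, words, model$k, model$pseudocount)
}

#' @export
bias_ratio.pwm_bias <- function(model, words) {
  pwm_word_prob(model$obs, words) / pwm_word_prob(model$exp, words)
}

#' Serialize a k-mer or PWM bias table to TSV
#'
#' Writes one row per word present in either multiset with its observed and
#' background probabilities and bias ratio.
#'
#' @param model A `kmer_bias` model.
#' @param path Output TSV path.
#' @export
write_bias_table <- function(model, path) {
  stopifnot(inherits(model, "kmer_bias"))
  words <- sort(unique(c(names(model$obs), names(model$exp))))
  df <- data.frame(
    word = words,
    obs_prob = kmer_prob(model$obs, model$n_obs, words, model$k,
                         model$pseudocount),
    exp_prob = kmer_prob(model$exp, model$n_exp, words, model$k,
                         model$pseudocount))
  df$bias <- df$obs_prob / df$exp_prob
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correct a cleavage track for sequence bias
#'
#' Applies `x_i = (y_i + 1) / (yhat_i * bhat(w[i]) + 1)` where `bhat(w[i])`
#' is the bias of the word at `i` divided by the summed bias over the 50-bp
#' window `[i-25, i+24]`. With the default `expected_counts_mode = "sum"`,
#' `yhat_i` is the total cleavage count in the window, so `yhat * bhat` is
#' the expected count at `i` under the bias model; `"mean"` divides the
#' window total by the window length (the formula read verbatim), which
#' leaves the correction nearly inert at typical sequencing depths because
#' the `+1` regularizer dominates. Windows truncated at the region edge are
#' renormalized over the available positions.
#'
#' @param track A [cleavage_track()].
#' @param model A `bias_model`, or `NULL` for no sequence bias (b == 1
#'   everywhere; `x` then only reflects the local-average normalization).
#' @param genome `DNAStringSet` covering the track region.
#' @param window Window size in bp (default 50; offsets `-w/2 .. w/2-1`).
#' @param expected_counts_mode `"mean"` (literal formula) or `"sum"`.
#' @return Numeric vector of corrected signal, same length as the region;
#'   all values positive.
#' @export
correct_track <- function(track, model, genome, window = 50L,
                          expected_counts_mode = c("sum", "mean")) {
  mode <- match.arg(expected_counts_mode)
  y <- track$counts
  n <- length(y)
  if (is.null(model)) {
    b <- rep(1, n)
  } else {
    pos <- seq(track$region$start, track$region$end)
    w <- extract_word(genome, pos, model$k, chrom = track$region$chrom,
                      strand = track$strand)
    b <- rep(1, n)
    ok <- !is.na(w)
    b[ok] <- bias_ratio(model, w[ok])
  }
  half <- window %/% 2L
  sy <- windowed_sum(y, half)
  sb <- windowed_sum(b, half)
  nw <- windowed_sum(rep(1, n), half)
  yhat <- if (mode == "mean") sy$sum / sy$n else sy$sum
  bhat <- b / sb$sum
  (y + 1) / (yhat * bhat + 1)
}

# sum over [i - half, i + half - 1], truncated at the vector edges
windowed_sum <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half - 1L)
  list(sum = cs[hi + 1L] - cs[lo], n = hi - lo + 1L)
}
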