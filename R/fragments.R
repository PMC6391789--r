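#' Genomic region helper
#'
#' Lightweight 1-based, inclusive region descriptor used by the signal
#' containers. Convert to/from `GRanges` with [as_granges()] /
#' [as_region()].
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return An object of class `gregion`.
#' @export
gregion <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, start >= 1L, end >= start)
  structure(list(chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end)),
            class = "gregion")
}

#' @export
length.gregion <- function(x) x$end - x$start + 1L

#' @rdname gregion
#' @param x A `gregion`.
#' @export
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' @rdname gregion
#' @param gr A length-one `GRanges`.
#' @export
as_region <- function(gr) {
  stopifnot(length(gr) == 1L)
  gregion(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Fragment-size classification scheme
#'
#' Paired-end ATAC-seq fragment lengths fall into modes corresponding to the
#' number of nucleosomes the fragment spans. The scheme assigns half-open-
#' on-left intervals: nucleosome-free `Nfr = (0, nfr_upper]`, mononucleosome
#' `1N = (nfr_upper, mono_upper]`, one-or-more `+1N = (nfr_upper, Inf]` and
#' two-or-more `+2N = (mono_upper, Inf]`; `All = (0, Inf]`.
#'
#' @param nfr_upper Upper bound (bp, inclusive) of the nucleosome-free class.
#' @param mono_upper Upper bound (bp, inclusive) of the mononucleosome class.
#' @return An object of class `fragment_scheme`.
#' @export
fragment_scheme <- function(nfr_upper = 145L, mono_upper = 307L) {
  stopifnot(nfr_upper > 0, mono_upper > nfr_upper)
  structure(list(nfr_upper = as.integer(nfr_upper),
                 mono_upper = as.integer(mono_upper)),
            class = "fragment_scheme")
}

FRAGMENT_CLASSES <- c("All", "Nfr", "1N", "+1N", "+2N")

#' Classify fragment lengths into nucleosome classes
#'
#' @param length Integer vector of fragment lengths (bp), all `>= 1`.
#' @param scheme A [fragment_scheme()].
#' @return Character vector over `{"Nfr","1N","+2N"}` (the partition classes;
#'   `All` and `+1N` are unions, test membership with [in_fragment_class()]).
#' @export
classify_fragment <- function(length, scheme = fragment_scheme()) {
  stopifnot(all(length >= 1))
  ifelse(length <= scheme$nfr_upper, "Nfr",
         ifelse(length <= scheme$mono_upper, "1N", "+2N"))
}

#' Test membership of fragment lengths in a (possibly union) class
#'
#' @inheritParams classify_fragment
#' @param class One of `"All"`, `"Nfr"`, `"1N"`, `"+1N"`, `"+2N"`.
#' @return Logical vector.
#' @export
in_fragment_class <- function(length, class, scheme = fragment_scheme()) {
  class <- match.arg(class, FRAGMENT_CLASSES)
  switch(class,
         All = length >= 1,
         Nfr = length >= 1 & length <= scheme$nfr_upper,
         "1N" = length > scheme$nfr_upper & length <= scheme$mono_upper,
         "+1N" = length > scheme$nfr_upper,
         "+2N" = length > scheme$mono_upper)
}

#' Estimate fragment-class boundaries from a fragment-length histogram
#'
#' Smooths the histogram with a moving average (window 11 bp) and locates
#' the local minima separating the first three modes of the fragment-size
#' distribution (nucleosome-free, mono-, di-nucleosome). Falls back to the
#' defaults (145, 307) with a warning when fewer than three modes are found.
#'
#' @param counts Integer vector; `counts[l]` is the number of fragments of
#'   length `l` (lengths `1..length(counts)`).
#' @param smooth_window Moving-average window (bp), odd.
#' @param min_prominence Minimum fraction of the global smoothed maximum a
#'   mode must reach to count as a mode.
#' @return A [fragment_scheme()].
#' @export
estimate_boundaries <- function(counts, smooth_window = 11L,
                                min_prominence = 0.05) {
  if (length(counts) == 0L || sum(counts) <= 0)
    stop("empty fragment-length histogram")
  n <- length(counts)
  half <- smooth_window %/% 2L
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- stats::filter(padded, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm <- as.numeric(sm)[half + seq_len(n)]
  # local maxima: strictly greater than one neighbour, >= the other
  is_max <- logical(n)
  for (i in 2:(n - 1L)) {
    is_max[i] <- sm[i] >= sm[i - 1L] && sm[i] >= sm[i + 1L] &&
      (sm[i] > sm[i - 1L] || sm[i] > sm[i + 1L])
  }
  modes <- which(is_max & sm >= min_prominence * max(sm))
  # collapse plateaus / near-duplicate modes closer than 30 bp
  if (length(modes) > 1L) {
    keep <- c(TRUE, diff(modes) > 30L)
    modes <- modes[keep]
  }
  if (length(modes) < 3L) {
    warning("fewer than three fragment-size modes detected; ",
            "using default boundaries (145, 307)")
    return(fragment_scheme())
  }
  modes <- modes[1:3]
  valley <- function(a, b) a + which.min(sm[a:b]) - 1L
  fragment_scheme(valley(modes[1], modes[2]), valley(modes[2], modes[3]))
}

#' Map a read 5' end to its cleavage-event position
#'
#' In ATAC-seq the centre of the Tn5 cleavage event sits at the fifth base of
#' the read, so forward-read start positions are shifted by +4 and
#' reverse-read 5' ends by -5. DNase-seq uses the read start unchanged.
#'
#' @param pos Integer vector of 5'-end positions (1-based).
#' @param strand `"+"` or `"-"` (recycled).
#' @param protocol `"atac"` or `"dnase"`.
#' @param shift Length-2 integer: forward and reverse shift applied in ATAC
#'   mode (default `c(4L, -5L)`).
#' @return Integer vector of cleavage positions.
#' @export
cleavage_position <- function(pos, strand, protocol = c("atac", "dnase"),
                              shift = c(4L, -5L)) {
  protocol <- match.arg(protocol)
  if (protocol == "dnase") return(as.integer(pos))
  as.integer(pos + ifelse(strand == "+", shift[1L], shift[2L]))
}

#' Read paired-end fragments from a coordinate-sorted BAM file
#'
#' Reconstructs fragments from properly paired reads: for the leftmost mate
#' (TLEN > 0) the fragment spans `[pos, pos + TLEN - 1]`. Reads below the
#' MAPQ floor are dropped.
#'
#' @param bam Path to an indexed BAM file.
#' @param region Optional [gregion()] restricting the query.
#' @param mapq Minimum mapping quality (default 30).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `length`.
#' @export
read_fragments <- function(bam, region = NULL, mapq = 30L) {
  what <- c("rname", "pos", "isize", "mapq")
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, flag = flag)
  } else {
    Rsamtools::ScanBamParam(what = what, flag = flag,
                            which = as_granges(region))
  }
  res <- Rsamtools::scanBam(bam, param = param)
  out <- lapply(res, function(r) {
    keep <- !is.na(r$isize) & r$isize > 0L & r$mapq >= mapq
    data.frame(chrom = as.character(r$rname[keep]),
               start = r$pos[keep],
               end = r$pos[keep] + r$isize[keep] - 1L,
               length = r$isize[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  unique(out)
}

#' Cleavage-event count track
#'
#' @param region A [gregion()].
#' @param strand `"+"` or `"-"`.
#' @param fragment_class One of the fragment classes.
#' @param counts Non-negative integer vector of length `length(region)`.
#' @param dropped Number of events dropped because the shifted position fell
#'   outside the chromosome.
#' @return An object of class `cleavage_track`.
#' @export
cleavage_track <- function(region, strand, fragment_class, counts,
                           dropped = 0L) {
  stopifnot(length(counts) == length(region), all(counts >= 0))
  structure(list(region = region, strand = strand,
                 fragment_class = fragment_class,
                 counts = as.numeric(counts), dropped = as.integer(dropped)),
            class = "cleavage_track")
}

#' @export
print.cleavage_track <- function(x, ...) {
  cat(sprintf("<cleavage_track> %s:%d-%d strand=%s class=%s events=%d\n",
              x$region$chrom, x$region$start, x$region$end, x$strand,
              x$fragment_class, sum(x$counts)))
  invisible(x)
}

#' Build a strand- and fragment-class-specific cleavage signal
#'
#' Counts cleavage events per position of `region`: every fragment whose
#' length falls in `fragment_class` contributes one forward event (at its
#' left end, shifted) and one reverse event (at its right end, shifted);
#' only the requested strand is counted.
#'
#' @param fragments `data.frame` as returned by [read_fragments()].
#' @param region A [gregion()].
#' @param strand `"+"` or `"-"`.
#' @param fragment_class Fragment class name (see [fragment_scheme()]).
#' @param scheme A [fragment_scheme()].
#' @param protocol `"atac"` or `"dnase"`.
#' @param shift ATAC shift pair, see [cleavage_position()].
#' @param chrom_len Optional chromosome length; shifted events outside
#'   `[1, chrom_len]` are dropped and counted in the track's `dropped` field.
#' @return A [cleavage_track()].
#' @export
build_signal <- function(fragments, region, strand = "+",
                         fragment_class = "All", scheme = fragment_scheme(),
                         protocol = "atac", shift = c(4L, -5L),
                         chrom_len = NULL) {
  fr <- fragments[fragments$chrom == region$chrom &
                    in_fragment_class(fragments$length, fragment_class,
                                      scheme), , drop = FALSE]
  pos <- if (strand == "+") {
    cleavage_position(fr$start, "+", protocol, shift)
  } else {
    cleavage_position(fr$end, "-", protocol, shift)
  }
  dropped <- 0L
  if (!is.null(chrom_len)) {
    off <- pos < 1L | pos > chrom_len
    dropped <- sum(off)
    pos <- pos[!off]
  }
  offs <- pos - region$start + 1L
  offs <- offs[offs >= 1L & offs <= length(region)]
  counts <- tabulate(offs, nbins = length(region))
  cleavage_track(region, strand, fragment_class, counts, dropped)
}
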