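# File-format boundary: FASTA via Biostrings, BED/narrowPeak/bigWig via
# rtracklayer, plus small deterministic text writers for outputs whose
# bytes must reproduce under a fixed seed.

#' Read a reference genome FASTA
#'
#' @param path FASTA path (an `.fai` index is created if absent).
#' @return `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(paste0(path, ".fai"))) Rsamtools::indexFa(path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read peak or site intervals from BED / narrowPeak
#'
#' @param path BED3+/BED6/narrowPeak path.
#' @return `GRanges` (with `name`/`score` columns when present).
#' @export
read_bed <- function(path) {
  if (grepl("\\.narrowPeak$", path)) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric",
                                      qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
}

#' Write intervals as BED6 (deterministic bytes)
#'
#' @param gr `GRanges`; metadata columns `name` and `score` are used when
#'   present.
#' @param path Output path.
#' @param name Fallback feature name.
#' @export
write_bed6 <- function(gr, path, name = "feature") {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) mc$name else rep(name, length(gr))
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = sprintf("%.4f", sc), strand = str)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-base signal as bedGraph (deterministic bytes)
#'
#' Runs of equal value are merged.
#'
#' @param values Numeric vector over `region`.
#' @param region [gregion()].
#' @param path Output path.
#' @export
write_bedgraph <- function(values, region, path) {
  r <- rle(sprintf("%.6g", values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(chrom = region$chrom,
                   start = region$start + starts - 2L,  # 0-based
                   end = region$start + ends - 1L,
                   value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a per-base signal as bigWig
#'
#' @inheritParams write_bedgraph
#' @param seqlen Chromosome length (for the bigWig header).
#' @export
write_bigwig <- function(values, region, seqlen, path) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GenomicRanges::GRanges(
    region$chrom,
    IRanges::IRanges(region$start + starts - 1L, region$start + ends - 1L),
    score = r$values)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, region$chrom)
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

#' Read a TF expression log2 fold-change table
#'
#' @param path TSV with columns `tf`, `log2fc` (header optional).
#' @return `data.frame(tf, log2fc)`.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("tf", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("tf", "log2fc")
  df[, 1:2]
}
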