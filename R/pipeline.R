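# End-to-end workflows: configuration, bias estimation, observation
# assembly, training, decoding, and the file-based run_* commands behind
# the command-line interface.

#' Footprinting run configuration
#'
#' Validated bundle of every tunable of the pipeline. Defaults follow the
#' method's standard operating point: ATAC protocol with the +4/-5 cut
#' shift, SLIM bias model with k = 8 and dependency distance d = 5,
#' strand-specific `All` decomposition, 9 HMM states, footprint length
#' filters 5-50 bp, motif FPR 1e-4, ChIP summit radius 100 bp, +/-500 bp
#' training windows.
#'
#' @param protocol `"atac"` or `"dnase"`.
#' @param bias_method `"slim"`, `"kmer"`, `"pwm"` or `"none"`.
#' @param k Bias word size (8 for ATAC; 6 is common for DNase k-mers).
#' @param d SLIM maximum dependency distance (< 6).
#' @param strategy Decomposition strategy name (see
#'   [decomposition_strategy()]).
#' @param strand_specific Keep strands as separate channels?
#' @param S Number of HMM states.
#' @param seed Seed for every stochastic step of a run.
#' @param shift ATAC cut-site shift pair.
#' @param scheme [fragment_scheme()] or `"estimate"` to derive boundaries
#'   from the library's fragment-size histogram.
#' @param min_len,max_len Footprint length filters (bp).
#' @param flank Training-window half width (bp).
#' @param bin_size,slope_window Signal normalization parameters.
#' @param expected_counts_mode `"mean"` or `"sum"` (see [correct_track()]).
#' @param fpr Motif-matching false-positive rate.
#' @param summit_radius ChIP summit labeling radius (bp).
#' @param mapq Minimum mapping quality for BAM fragments.
#' @param pseudocount Bias-estimator pseudocount.
#' @param max_iter,tol Baum-Welch stopping rule.
#' @return An object of class `footprint_config`.
#' @export
footprint_config <- function(protocol = c("atac", "dnase"),
                             bias_method = c("slim", "kmer", "pwm", "none"),
                             k = 8L, d = 5L, strategy = "All",
                             strand_specific = TRUE, S = 9L, seed = 1L,
                             shift = c(4L, -5L), scheme = fragment_scheme(),
                             min_len = 5L, max_len = 50L, flank = 500L,
                             bin_size = 10000L, slope_window = 9L,
                             expected_counts_mode = "sum", fpr = 1e-4,
                             summit_radius = 100L, mapq = 30L,
                             pseudocount = 1, max_iter = 100L, tol = 1e-4) {
  protocol <- match.arg(protocol)
  bias_method <- match.arg(bias_method)
  stopifnot(k >= 1L, d >= 1L, d <= 5L, S >= 2L, min_len >= 1L,
            max_len >= min_len, fpr > 0, fpr < 1)
  structure(list(protocol = protocol, bias_method = bias_method,
                 k = as.integer(k), d = as.integer(d), strategy = strategy,
                 strand_specific = strand_specific, S = as.integer(S),
                 seed = as.integer(seed), shift = as.integer(shift),
                 scheme = scheme, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), flank = as.integer(flank),
                 bin_size = as.integer(bin_size),
                 slope_window = as.integer(slope_window),
                 expected_counts_mode = expected_counts_mode, fpr = fpr,
                 summit_radius = as.integer(summit_radius),
                 mapq = as.integer(mapq), pseudocount = pseudocount,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "footprint_config")
}

#' Serialize a run configuration as JSON
#'
#' Written into every run's output directory for reproducibility.
#'
#' @param config A [footprint_config()].
#' @param path Output JSON path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$scheme <- if (inherits(x$scheme, "fragment_scheme"))
    unclass(x$scheme) else x$scheme
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_scheme <- function(fragments, config) {
  if (inherits(config$scheme, "fragment_scheme")) return(config$scheme)
  h <- tabulate(pmin(fragments$length, 1000L), nbins = 1000L)
  estimate_boundaries(h)
}

#' Estimate the library's cleavage-bias model
#'
#' Builds strand-specific All-fragment cleavage tracks over the peaks,
#' collects the observed and background word multisets and fits the
#' estimator named in the configuration.
#'
#' @param fragments Fragment `data.frame` (see [read_fragments()]).
#' @param peaks `GRanges` of accessible regions.
#' @param genome `DNAStringSet`.
#' @param config A [footprint_config()].
#' @return A `bias_model`, or `NULL` for `bias_method = "none"`.
#' @export
estimate_bias_model <- function(fragments, peaks, genome, config) {
  if (config$bias_method == "none") return(NULL)
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  tracks <- list()
  for (i in seq_along(peaks)) {
    reg <- as_region(peaks[i])
    for (s in c("+", "-")) {
      tracks[[length(tracks) + 1L]] <-
        build_signal(fragments, reg, s, "All", protocol = config$protocol,
                     shift = config$shift, chrom_len = L)
    }
  }
  w <- collect_words(tracks, peaks, genome, config$k)
  switch(config$bias_method,
         kmer = estimate_kmer(w$obs, w$exp, config$k, config$pseudocount),
         pwm = estimate_pwm(w$obs, w$exp, config$pseudocount),
         slim = fit_slim(w$obs, w$exp, config$k, config$d,
                         seed = config$seed,
                         pseudocount = config$pseudocount))
}

# corrected signal tracks for one region, keyed "class/strand"
region_signals <- function(fragments, region, genome, bias_model, config,
                           pad = 100L) {
  chrom_len <- Biostrings::width(genome)[1]
  strategy <- decomposition_strategy(config$strategy,
                                     config$strand_specific)
  scheme <- resolve_scheme(fragments, config)
  ext <- gregion(region$chrom, max(1L, region$start - pad),
                 min(chrom_len, region$end + pad))
  cut <- (region$start:region$end) - ext$start + 1L
  out <- list()
  for (cls in strategy$classes) {
    if (config$strand_specific) {
      for (s in c("+", "-")) {
        tr <- build_signal(fragments, ext, s, cls, scheme, config$protocol,
                           config$shift, chrom_len)
        x <- correct_track(tr, bias_model, genome,
                           expected_counts_mode = config$expected_counts_mode)
        out[[paste(cls, s, sep = "/")]] <- x[cut]
      }
    } else {
      trp <- build_signal(fragments, ext, "+", cls, scheme, config$protocol,
                          config$shift, chrom_len)
      trm <- build_signal(fragments, ext, "-", cls, scheme, config$protocol,
                          config$shift, chrom_len)
      pooled <- cleavage_track(ext, "+", cls, trp$counts + trm$counts)
      x <- correct_track(pooled, bias_model, genome,
                         expected_counts_mode = config$expected_counts_mode)
      out[[paste(cls, "*", sep = "/")]] <- x[cut]
    }
  }
  out
}

#' Assemble the observation matrix for a region
#'
#' @inheritParams estimate_bias_model
#' @param region [gregion()] to cover.
#' @param bias_model Fitted bias model (or `NULL`).
#' @return Observation matrix, one row per region position.
#' @export
build_observations <- function(fragments, region, genome, bias_model,
                               config) {
  strategy <- decomposition_strategy(config$strategy,
                                     config$strand_specific)
  sig <- region_signals(fragments, region, genome, bias_model, config)
  assemble_observations(sig, strategy, config$bin_size, config$slope_window)
}

#' Train a footprint model from ChIP-supported motif sites
#'
#' @inheritParams estimate_bias_model
#' @param mpbs `GRanges` of the training TF's motif-predicted binding
#'   sites.
#' @param chip_peaks `GRanges` of the TF's ChIP-seq peaks.
#' @param bias_model Fitted bias model (or `NULL`).
#' @return A trained [footprint_hmm()].
#' @export
train_model <- function(fragments, genome, mpbs, chip_peaks, bias_model,
                        config) {
  chrom_len <- Biostrings::width(genome)[1]
  supported <- mpbs[IRanges::overlapsAny(mpbs, chip_peaks)]
  if (length(supported) == 0L) stop("no ChIP-supported MPBS for training")
  windows <- list()
  for (i in seq_along(supported)) {
    cen <- (GenomicRanges::start(supported[i]) +
              GenomicRanges::end(supported[i])) %/% 2L
    lo <- cen - config$flank
    hi <- cen + config$flank
    if (lo < 1L + 150L || hi > chrom_len - 150L) next
    reg <- gregion(as.character(GenomicRanges::seqnames(supported[i])),
                   lo, hi)
    obs <- build_observations(fragments, reg, genome, bias_model, config)
    labels <- (lo:hi) >= GenomicRanges::start(supported[i]) &
      (lo:hi) <= GenomicRanges::end(supported[i])
    windows[[length(windows) + 1L]] <- list(obs = obs, labels = labels)
  }
  if (length(windows) == 0L) stop("no training window fits the chromosome")
  train_footprint_hmm(windows, config$S, seed = config$seed,
                      max_iter = config$max_iter, tol = config$tol)
}

#' Call footprints in peak regions
#'
#' Full in-memory pipeline: bias estimation (unless a model is supplied),
#' observation assembly per peak, Viterbi decoding, footprint extraction
#' and tag-count scoring.
#'
#' @inheritParams estimate_bias_model
#' @param model A trained [footprint_hmm()]; or `NULL` to train on
#'   `train_mpbs` / `train_chip`.
#' @param bias_model Optional pre-fitted bias model (estimated from the
#'   library when `NULL` and `bias_method != "none"`).
#' @param train_mpbs,train_chip Training labels (used when `model` is
#'   `NULL`).
#' @return `list(footprints, model, bias_model)`; footprints are `GRanges`
#'   with `score` (tag count) and `name` metadata.
#' @export
call_footprints <- function(fragments, peaks, genome, config, model = NULL,
                            bias_model = NULL, train_mpbs = NULL,
                            train_chip = NULL) {
  if (is.null(bias_model) && config$bias_method != "none")
    bias_model <- estimate_bias_model(fragments, peaks, genome, config)
  if (is.null(model)) {
    if (is.null(train_mpbs) || is.null(train_chip))
      stop("either a trained model or training labels are required")
    model <- train_model(fragments, genome, train_mpbs, train_chip,
                         bias_model, config)
  }
  fps <- list()
  for (i in seq_along(peaks)) {
    reg <- as_region(peaks[i])
    obs <- build_observations(fragments, reg, genome, bias_model, config)
    path <- viterbi_decode(model, obs)
    fp <- extract_footprints(path, reg, model, config$min_len,
                             config$max_len)
    if (length(fp) == 0L) next
    sig <- region_signals(fragments, reg, genome, bias_model, config)
    tag_keys <- grep("^(All|Nfr)/", names(sig), value = TRUE)
    tag <- Reduce(`+`, sig[tag_keys])
    S4Vectors::mcols(fp)$score <-
      tag_count_score(GenomicRanges::start(fp), GenomicRanges::end(fp),
                      tag, reg)
    fps[[length(fps) + 1L]] <- fp
  }
  footprints <- if (length(fps) == 0L) {
    GenomicRanges::GRanges(score = numeric(0))
  } else {
    do.call(c, fps)
  }
  if (length(footprints) > 0)
    S4Vectors::mcols(footprints)$name <-
      sprintf("footprint_%s_%04d", config$strategy,
              seq_along(footprints))
  list(footprints = footprints, model = model, bias_model = bias_model)
}

#' Run the footprinting pipeline from files
#'
#' Reads BAM/BED/FASTA inputs, calls footprints and writes
#' `footprints.bed`, `model.json` and `config.json` into `out_dir`.
#' Outputs are byte-identical for identical inputs, configuration and
#' seed.
#'
#' @param bam Indexed BAM of the library.
#' @param peaks_bed Peak intervals (BED/narrowPeak).
#' @param fasta Reference genome FASTA.
#' @param out_dir Output directory (created).
#' @param config A [footprint_config()].
#' @param model_json Optional pre-trained model (JSON, see [write_hmm()]).
#' @param train_mpbs_bed,train_chip_bed Training-label BED files (needed
#'   when `model_json` is absent).
#' @return Invisible list of output paths.
#' @export
run_footprint <- function(bam, peaks_bed, fasta, out_dir, config,
                          model_json = NULL, train_mpbs_bed = NULL,
                          train_chip_bed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(fasta)
  peaks <- read_bed(peaks_bed)
  fragments <- read_fragments(bam, mapq = config$mapq)
  model <- if (!is.null(model_json)) read_hmm(model_json) else NULL
  mpbs <- if (!is.null(train_mpbs_bed)) read_bed(train_mpbs_bed) else NULL
  chip <- if (!is.null(train_chip_bed)) read_bed(train_chip_bed) else NULL
  res <- call_footprints(fragments, peaks, genome, config, model,
                         train_mpbs = mpbs, train_chip = chip)
  out <- list(footprints = file.path(out_dir, "footprints.bed"),
              model = file.path(out_dir, "model.json"),
              config = file.path(out_dir, "config.json"))
  write_bed6(res$footprints, out$footprints)
  write_hmm(res$model, out$model)
  write_config(config, out$config)
  invisible(out)
}

#' Write corrected signal tracks from files
#'
#' One bedGraph (and optionally bigWig) per fragment class and strand of
#' the configured decomposition, bias-corrected.
#'
#' @inheritParams run_footprint
#' @param bigwig Also write bigWig copies?
#' @return Invisible vector of output paths.
#' @export
run_tracks <- function(bam, peaks_bed, fasta, out_dir, config,
                       bigwig = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(fasta)
  peaks <- read_bed(peaks_bed)
  fragments <- read_fragments(bam, mapq = config$mapq)
  bias_model <- estimate_bias_model(fragments, peaks, genome, config)
  paths <- character(0)
  for (i in seq_along(peaks)) {
    reg <- as_region(peaks[i])
    sig <- region_signals(fragments, reg, genome, bias_model, config)
    for (key in names(sig)) {
      tag <- gsub("[/+]", "_", gsub("-", "m", gsub("\\*", "both", key)))
      p <- file.path(out_dir, sprintf("signal_peak%d_%s.bedGraph", i, tag))
      write_bedgraph(sig[[key]], reg, p)
      paths <- c(paths, p)
      if (bigwig) {
        bw <- sub("\\.bedGraph$", ".bw", p)
        write_bigwig(sig[[key]], reg, Biostrings::width(genome)[1], bw)
        paths <- c(paths, bw)
      }
    }
  }
  write_config(config, file.path(out_dir, "config.json"))
  invisible(paths)
}

#' Evaluate footprint calls against ChIP-labeled motif sites (files)
#'
#' @param footprints_bed Footprint BED (scores = tag counts).
#' @param mpbs_bed MPBS BED.
#' @param summits_bed ChIP summit BED.
#' @param out_tsv Output TSV path (`measure`, `value`).
#' @param summit_radius Labeling radius (bp).
#' @return The evaluation `data.frame`, invisibly.
#' @export
run_evaluate <- function(footprints_bed, mpbs_bed, summits_bed, out_tsv,
                         summit_radius = 100L) {
  fps <- read_bed(footprints_bed)
  mpbs <- read_bed(mpbs_bed)
  summits <- read_bed(summits_bed)
  mpbs <- label_with_chipseq(mpbs, summits, summit_radius)
  res <- evaluate_footprints(mpbs, fps)
  write.table(res, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Differential TF activity between two conditions (files)
#'
#' Computes bias-corrected signals per condition over the full chromosome,
#' restricts each TF's MPBS (grouped by the BED `name` column) to
#' footprint-supported sites, and writes the differential-activity table.
#'
#' @param bam1,bam2 Condition libraries (indexed BAM).
#' @param footprints1_bed,footprints2_bed Footprint calls per condition.
#' @param mpbs_bed MPBS BED; the `name` column carries the TF.
#' @param peaks_bed Accessible peaks (for bias estimation).
#' @param fasta Reference genome FASTA.
#' @param out_tsv Output TSV path.
#' @param config A [footprint_config()].
#' @param expression_tsv Optional TF expression log2FC table.
#' @return The [differential_activity()] table, invisibly.
#' @export
run_differential <- function(bam1, bam2, footprints1_bed, footprints2_bed,
                             mpbs_bed, peaks_bed, fasta, out_tsv, config,
                             expression_tsv = NULL) {
  genome <- read_genome(fasta)
  peaks <- read_bed(peaks_bed)
  fp1 <- read_bed(footprints1_bed)
  fp2 <- read_bed(footprints2_bed)
  mpbs <- read_bed(mpbs_bed)
  expression <- if (!is.null(expression_tsv)) read_expression(expression_tsv)
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  whole <- gregion(chrom, 1L, L)
  cond_signal <- function(bam) {
    fragments <- read_fragments(bam, mapq = config$mapq)
    bias_model <- estimate_bias_model(fragments, peaks, genome, config)
    trp <- build_signal(fragments, whole, "+", "All",
                        protocol = config$protocol, shift = config$shift,
                        chrom_len = L)
    trm <- build_signal(fragments, whole, "-", "All",
                        protocol = config$protocol, shift = config$shift,
                        chrom_len = L)
    pooled <- cleavage_track(whole, "+", "All", trp$counts + trm$counts)
    correct_track(pooled, bias_model, genome,
                  expected_counts_mode = config$expected_counts_mode)
  }
  sig1 <- cond_signal(bam1)
  sig2 <- cond_signal(bam2)
  tfs <- S4Vectors::mcols(mpbs)$name
  if (is.null(tfs)) stop("mpbs BED needs a name column carrying the TF")
  site_sets <- lapply(split(seq_along(mpbs), tfs), function(idx)
    tf_condition_set(mpbs[idx], fp1, fp2, sig1, sig2, whole))
  res <- differential_activity(site_sets, expression)
  write.table(res, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
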