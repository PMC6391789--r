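# Differential TF activity between two conditions.
#
# The activity score of a TF is the mean, over its footprint-supported
# binding sites, of a protection term (flank minus footprint cleavage) plus
# an openness term (total cleavage within +/-100 bp). Condition scores are
# made comparable by DESeq-style median-of-ratios size factors, and the
# per-site contributions feed a Welch t-test with Benjamini-Hochberg
# correction and an expression-fold-change filter.

#' Per-site activity contributions
#'
#' For a site `[fl, fr]` of width `e` the contribution is
#' `0.5 * sum(x[fl-e-1 .. fl-1]) + 0.5 * sum(x[fr+1 .. fr+e+1])
#'  - sum(x[fl .. fr]) + sum(x[fl-100 .. fr+100])`
#' (protection plus openness). Sites whose `+/- (e + 101)` window leaves the
#' signal region are skipped with a message.
#'
#' @param sites `GRanges` (or `data.frame` with `start`, `end`) of
#'   footprint-supported binding sites of one TF.
#' @param signal Bias-corrected signal over `region`.
#' @param region [gregion()].
#' @return Numeric vector of per-site contributions (possibly shorter than
#'   `sites` if edge sites were skipped).
#' @export
site_activity <- function(sites, signal, region) {
  if (inherits(sites, "GRanges")) {
    fl <- GenomicRanges::start(sites)
    fr <- GenomicRanges::end(sites)
  } else {
    fl <- sites$start
    fr <- sites$end
  }
  e <- fr - fl + 1L
  lo_need <- fl - pmax(e + 1L, 100L)
  hi_need <- fr + pmax(e + 1L, 100L)
  ok <- lo_need >= region$start & hi_need <= region$end
  if (any(!ok))
    message(sum(!ok), " site(s) too close to the region edge; skipped")
  idx <- function(p) p - region$start + 1L
  vapply(which(ok), function(i) {
    left <- sum(signal[idx(fl[i] - e[i] - 1L):idx(fl[i] - 1L)])
    right <- sum(signal[idx(fr[i] + 1L):idx(fr[i] + e[i] + 1L)])
    foot <- sum(signal[idx(fl[i]):idx(fr[i])])
    open <- sum(signal[idx(fl[i] - 100L):idx(fr[i] + 100L)])
    0.5 * left + 0.5 * right - foot + open
  }, numeric(1))
}

#' TF activity score
#'
#' Mean of the per-site contributions ([site_activity()]).
#'
#' @inheritParams site_activity
#' @return The ACT score (scalar).
#' @export
activity_score <- function(sites, signal, region) {
  mean(site_activity(sites, signal, region))
}

#' Median-of-ratios size factors for two conditions
#'
#' DESeq-style: each TF's geometric mean across the two conditions is the
#' reference; the size factor of a condition is the median over TFs of
#' `ACT / reference`. TFs with non-positive ACT in either condition are
#' excluded from the reference.
#'
#' @param act1,act2 Named numeric vectors of per-TF ACT scores (same TFs).
#' @return `c(omega1, omega2)`.
#' @export
size_factors <- function(act1, act2) {
  stopifnot(length(act1) == length(act2))
  ok <- act1 > 0 & act2 > 0
  if (sum(ok) < 2) stop("need >= 2 TFs with positive ACT in both conditions")
  ref <- sqrt(act1[ok] * act2[ok])
  c(median(act1[ok] / ref), median(act2[ok] / ref))
}

#' Differential activity score
#'
#' `delta_act = ACT2 / omega2 - ACT1 / omega1`; positive values favor
#' condition 2.
#'
#' @param act1,act2 Per-TF ACT scores (scalars or vectors).
#' @param omega Size factors from [size_factors()].
#' @return Signed difference.
#' @export
delta_act <- function(act1, act2, omega) {
  stopifnot(all(omega > 0))
  act2 / omega[2] - act1 / omega[1]
}

#' Binding sites supported by footprints in either condition
#'
#' @param mpbs `GRanges` of a TF's motif-predicted binding sites.
#' @param footprints1,footprints2 Footprint calls of the two conditions.
#' @return The subset of `mpbs` overlapping (>= 1 bp) a footprint from at
#'   least one condition.
#' @export
footprint_supported_sites <- function(mpbs, footprints1, footprints2) {
  sup <- IRanges::overlapsAny(mpbs, footprints1, ignore.strand = TRUE) |
    IRanges::overlapsAny(mpbs, footprints2, ignore.strand = TRUE)
  mpbs[sup]
}

#' Differential TF activity test across two conditions
#'
#' For every TF: ACT per condition, median-of-ratios normalization, delta
#' ACT, a Welch t-test on the size-factor-normalized per-site contributions,
#' BH adjustment across TFs, and an expression-fold-change filter. A TF is
#' flagged when `padj < p_cutoff` and `|log2FC| > lfc_cutoff`; TFs missing
#' from the expression table are retained with `expression_unfiltered =
#' TRUE` (and flagged on the p-value alone).
#'
#' @param site_sets Named list (per TF) of `list(sites1, signal1, region1,
#'   sites2, signal2, region2)`; or use [tf_condition_set()] to build the
#'   entries.
#' @param expression Optional `data.frame` with columns `tf`, `log2fc`.
#' @param p_cutoff,lfc_cutoff Flagging thresholds (0.05, 0.5).
#' @return `data.frame` (one row per TF): `tf`, `act1`, `act2`,
#'   `delta_act`, `p`, `padj`, `log2fc`, `expression_unfiltered`,
#'   `flagged`.
#' @export
differential_activity <- function(site_sets, expression = NULL,
                                  p_cutoff = 0.05, lfc_cutoff = 0.5) {
  tfs <- names(site_sets)
  contrib <- lapply(site_sets, function(s) {
    list(c1 = site_activity(s$sites1, s$signal1, s$region1),
         c2 = site_activity(s$sites2, s$signal2, s$region2))
  })
  act1 <- vapply(contrib, function(x) mean(x$c1), numeric(1))
  act2 <- vapply(contrib, function(x) mean(x$c2), numeric(1))
  omega <- size_factors(act1, act2)
  dact <- delta_act(act1, act2, omega)
  p <- vapply(tfs, function(tf) {
    x1 <- contrib[[tf]]$c1 / omega[1]
    x2 <- contrib[[tf]]$c2 / omega[2]
    if (length(x1) < 2 || length(x2) < 2) return(NA_real_)
    if (sd(x1) == 0 && sd(x2) == 0) {
      return(if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else 0)
    }
    t.test(x1, x2)$p.value
  }, numeric(1))
  padj <- p.adjust(p, method = "BH")
  lfc <- rep(NA_real_, length(tfs))
  if (!is.null(expression)) {
    m <- match(tfs, expression$tf)
    lfc <- expression$log2fc[m]
  }
  unfiltered <- is.na(lfc)
  flagged <- !is.na(padj) & padj < p_cutoff &
    (unfiltered | abs(lfc) > lfc_cutoff)
  data.frame(tf = tfs, act1 = unname(act1), act2 = unname(act2),
             delta_act = unname(dact), p = unname(p), padj = unname(padj),
             log2fc = lfc, expression_unfiltered = unfiltered,
             flagged = flagged, row.names = NULL)
}

#' Assemble one TF's two-condition site set
#'
#' Convenience builder for the [differential_activity()] input.
#'
#' @param mpbs The TF's motif-predicted binding sites.
#' @param footprints1,footprints2 Footprint calls per condition.
#' @param signal1,signal2 Corrected signals per condition.
#' @param region1,region2 Regions the signals cover.
#' @return List consumed by [differential_activity()].
#' @export
tf_condition_set <- function(mpbs, footprints1, footprints2,
                             signal1, signal2, region1,
                             region2 = region1) {
  sites <- footprint_supported_sites(mpbs, footprints1, footprints2)
  list(sites1 = sites, signal1 = signal1, region1 = region1,
       sites2 = sites, signal2 = signal2, region2 = region2)
}
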