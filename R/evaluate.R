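# Footprint evaluation against ChIP-labeled motif sites: partial AUC /
# AUPR over tag-count-ranked MPBS, and the combined ranking score used to
# compare methods across the six measures.

#' Partial area under the ROC curve
#'
#' Trapezoidal area of the ROC restricted to `FPR <= max_fpr`, normalized
#' by `max_fpr` so a perfect ranking scores 1 at any cutoff. Tied scores are
#' grouped (one ROC vertex per distinct score).
#'
#' @param scores Numeric predicted scores (higher = more confident).
#' @param labels Logical (or 0/1) truth labels.
#' @param max_fpr Upper FPR bound: 1, 0.1 or 0.01 in the standard harness
#'   (any value in (0, 1] is accepted).
#' @return Partial AUC in `[0, 1]`.
#' @export
auc_at_fpr <- function(scores, labels, max_fpr = 1) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0) stop("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  lb <- labels[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lb)
  fp <- cumsum(!lb)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  area <- 0
  for (i in 2:length(fpr)) {
    if (fpr[i - 1] >= max_fpr) break
    x0 <- fpr[i - 1]
    x1 <- min(fpr[i], max_fpr)
    # linear interpolation of the ROC segment at the clip point
    y0 <- tpr[i - 1]
    y1 <- if (fpr[i] == fpr[i - 1]) tpr[i] else
      y0 + (tpr[i] - y0) * (x1 - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / max_fpr
}

#' Partial area under the precision-recall curve
#'
#' Step-curve interpolation: precision is held constant over each recall
#' increment (one vertex per distinct score), the area is truncated at
#' `max_recall` and normalized by it.
#'
#' @inheritParams auc_at_fpr
#' @param max_recall Upper recall bound (1, 0.1 or 0.01 in the harness).
#' @return Partial AUPR in `[0, 1]`.
#' @export
aupr_at_recall <- function(scores, labels, max_recall = 1) {
  labels <- as.logical(labels)
  P <- sum(labels)
  if (P == 0 || sum(!labels) == 0)
    stop("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  lb <- labels[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lb)
  n <- seq_along(lb)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tp[last] / P
  precision <- tp[last] / n[last]
  area <- 0
  prev_r <- 0
  for (i in seq_along(recall)) {
    if (prev_r >= max_recall) break
    r <- min(recall[i], max_recall)
    area <- area + (r - prev_r) * precision[i]
    prev_r <- r
  }
  area / max_recall
}

#' Combined ranking score across the six evaluation measures
#'
#' `sum_m -log(r_m / (N + 1))` (natural log) over the six measures (AUC and
#' AUPR at 100/10/1%), where `r_m` is the method's rank for measure `m`
#' among `N` methods. Higher is better; the score strictly decreases as any
#' rank worsens.
#'
#' @param ranks Numeric vector of per-measure ranks (length 6 in the
#'   standard harness), each in `[1, N]`.
#' @param n_methods Number of methods compared (`N`).
#' @return The ranking score.
#' @export
ranking_score <- function(ranks, n_methods) {
  stopifnot(all(ranks >= 1), all(ranks <= n_methods))
  sum(-log(ranks / (n_methods + 1)))
}

#' Score labeled MPBS by overlapping footprints (tag count)
#'
#' Every labeled MPBS receives the tag-count score of the union of its own
#' interval and any overlapping footprint, or 0 when no footprint overlaps.
#'
#' @param mpbs Labeled `GRanges` (see [label_with_chipseq()]).
#' @param footprints `GRanges` of predicted footprints.
#' @param signal Bias-corrected signal over `region`; when `NULL`, the
#'   footprints' `score` metadata column (tag counts written at call time)
#'   is used instead.
#' @param region [gregion()].
#' @return `data.frame` with columns `score` and `label`, one row per MPBS.
#' @export
score_mpbs <- function(mpbs, footprints, signal = NULL, region = NULL) {
  ov <- GenomicRanges::findOverlaps(mpbs, footprints, ignore.strand = TRUE)
  score <- numeric(length(mpbs))
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (is.null(signal)) {
      sc <- S4Vectors::mcols(footprints)$score[sh]
      if (is.null(sc)) stop("footprints carry no score and no signal given")
    } else {
      lo <- pmin(GenomicRanges::start(mpbs)[qh],
                 GenomicRanges::start(footprints)[sh])
      hi <- pmax(GenomicRanges::end(mpbs)[qh],
                 GenomicRanges::end(footprints)[sh])
      sc <- tag_count_score(lo, hi, signal, region)
    }
    for (i in seq_along(qh)) score[qh[i]] <- max(score[qh[i]], sc[i])
  }
  data.frame(score = score, label = S4Vectors::mcols(mpbs)$true_site)
}

#' Evaluate footprint predictions against labeled MPBS
#'
#' Computes the six standard measures (partial AUC and AUPR at 100%, 10%
#' and 1%).
#'
#' @inheritParams score_mpbs
#' @return `data.frame` with columns `measure`, `value`.
#' @export
evaluate_footprints <- function(mpbs, footprints, signal = NULL,
                                region = NULL) {
  rs <- score_mpbs(mpbs, footprints, signal, region)
  data.frame(
    measure = c("auc_100", "auc_10", "auc_1",
                "aupr_100", "aupr_10", "aupr_1"),
    value = c(auc_at_fpr(rs$score, rs$label, 1),
              auc_at_fpr(rs$score, rs$label, 0.1),
              auc_at_fpr(rs$score, rs$label, 0.01),
              aupr_at_recall(rs$score, rs$label, 1),
              aupr_at_recall(rs$score, rs$label, 0.1),
              aupr_at_recall(rs$score, rs$label, 0.01)))
}
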