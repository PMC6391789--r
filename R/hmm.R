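# Semi-supervised footprint HMM.
#
# A fully connected S-state HMM with multivariate Gaussian emissions (full
# covariance) over the observation channels. One designated state models the
# FOOTPRINT. Training is semi-supervised: the FOOTPRINT emission is
# estimated from labeled positions (motif intervals under ChIP-seq peaks)
# and held fixed, while Baum-Welch re-estimates the remaining states and all
# transitions; labeled positions are clamped to the FOOTPRINT state during
# the E-step. Decoding uses the Viterbi algorithm; ties break toward the
# lower state index.

#' Footprint HMM constructor
#'
#' @param init Initial state distribution (length S, sums to 1).
#' @param trans S x S transition matrix (rows sum to 1).
#' @param means S x d matrix of emission means.
#' @param covs List of S `d x d` covariance matrices (symmetric positive
#'   definite).
#' @param footprint_state Index of the FOOTPRINT state.
#' @return An object of class `footprint_hmm`.
#' @export
footprint_hmm <- function(init, trans, means, covs, footprint_state = 1L) {
  S <- length(init)
  stopifnot(abs(sum(init) - 1) < 1e-9,
            nrow(trans) == S, ncol(trans) == S,
            all(abs(rowSums(trans) - 1) < 1e-9),
            nrow(means) == S, length(covs) == S,
            footprint_state >= 1L, footprint_state <= S)
  structure(list(S = S, d = ncol(means), init = init, trans = trans,
                 means = means, covs = covs,
                 footprint_state = as.integer(footprint_state)),
            class = "footprint_hmm")
}

#' @export
print.footprint_hmm <- function(x, ...) {
  cat(sprintf("<footprint_hmm> S=%d d=%d footprint_state=%d\n",
              x$S, x$d, x$footprint_state))
  invisible(x)
}

# T x S matrix of Gaussian log-densities
emission_logdens <- function(model, obs) {
  obs <- as.matrix(obs)
  Tn <- nrow(obs)
  B <- matrix(0, Tn, model$S)
  for (s in seq_len(model$S)) {
    ch <- chol(model$covs[[s]])
    z <- backsolve(ch, t(obs) - model$means[s, ], transpose = TRUE)
    B[, s] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) -
      0.5 * model$d * log(2 * pi)
  }
  if (any(!is.finite(B))) stop("non-finite emission density")
  B
}

# scaled forward-backward; labels (logical or NA) clamp positions to the
# footprint state. Returns gamma, xi sum, log-likelihood.
forward_backward <- function(model, obs, labels = NULL) {
  B <- emission_logdens(model, obs)
  Tn <- nrow(B)
  S <- model$S
  if (!is.null(labels)) {
    lab <- which(labels)
    if (length(lab) > 0) B[lab, -model$footprint_state] <- -Inf
  }
  mx <- apply(B, 1, max)
  b <- exp(B - mx)
  alpha <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- model$init * b[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% model$trans)[1, ] * b[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, S)
  beta[Tn, ] <- 1
  xi <- matrix(0, S, S)
  for (t in (Tn - 1):1) {
    bb <- b[t + 1, ] * beta[t + 1, ]
    m <- model$trans * (alpha[t, ] %o% bb)
    xi <- xi + m / sum(m)
    beta[t, ] <- (model$trans %*% bb)[, 1] / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(mx))
}

# weighted mean/covariance M-step for one state
weighted_gaussian <- function(obs, w, ridge_eps = 1e-6, ridge = 1e-4) {
  wsum <- sum(w)
  mu <- colSums(obs * w) / wsum
  z <- sweep(obs, 2, mu)
  cov <- crossprod(z * w, z) / wsum
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge_eps) cov <- cov + diag(ridge, ncol(obs))
  list(mean = mu, cov = cov)
}

#' Build training windows around ChIP-supported motif sites
#'
#' One window per motif-predicted binding site (MPBS) overlapping a ChIP-seq
#' peak: the observation matrix rows for motif-center +/- `flank`, with the
#' motif interval labeled FOOTPRINT.
#'
#' @param mpbs `GRanges` of motif-predicted binding sites.
#' @param chip_peaks `GRanges` of ChIP-seq peaks (training evidence).
#' @param obs Observation matrix covering `region` (one row per position).
#' @param region [gregion()] that `obs` covers.
#' @param flank Half-window in bp (default 500; window length `2*flank+1`).
#' @return List of windows, each `list(obs, labels)` with `labels` logical
#'   over the window marking the motif interval.
#' @export
make_training_windows <- function(mpbs, chip_peaks, obs, region,
                                  flank = 500L) {
  supported <- IRanges::overlapsAny(mpbs, chip_peaks)
  mpbs <- mpbs[supported]
  if (length(mpbs) == 0L) stop("no ChIP-supported MPBS for training")
  out <- list()
  for (i in seq_along(mpbs)) {
    cen <- (GenomicRanges::start(mpbs[i]) + GenomicRanges::end(mpbs[i])) %/% 2L
    lo <- cen - flank
    hi <- cen + flank
    if (lo < region$start || hi > region$end) next
    rows <- (lo:hi) - region$start + 1L
    labels <- (lo:hi) >= GenomicRanges::start(mpbs[i]) &
      (lo:hi) <= GenomicRanges::end(mpbs[i])
    out[[length(out) + 1L]] <- list(obs = obs[rows, , drop = FALSE],
                                    labels = labels)
  }
  if (length(out) == 0L) stop("no training window fits inside the region")
  out
}

#' Train the footprint HMM semi-supervised
#'
#' The FOOTPRINT state's Gaussian is estimated from labeled positions only
#' and held fixed; Baum-Welch updates the other `S - 1` states and all
#' transitions, with labeled positions clamped to the FOOTPRINT state in
#' every E-step. Initial parameters come from an M-step over random
#' posteriors (labels excepted). The training log-likelihood is monotone
#' non-decreasing.
#'
#' @param windows List of training windows (see [make_training_windows()]).
#' @param S Number of states (`>= 2`).
#' @param seed Seed for the random initial posteriors.
#' @param max_iter,tol Baum-Welch stopping rule (relative log-likelihood
#'   change).
#' @param footprint_state Index reserved for the FOOTPRINT state.
#' @return A [footprint_hmm()] with attributes `loglik` (per-iteration
#'   trace) and `converged`.
#' @export
train_footprint_hmm <- function(windows, S, seed = 1L, max_iter = 100L,
                                tol = 1e-4, footprint_state = 1L) {
  stopifnot(S >= 2L, length(windows) > 0)
  d <- ncol(windows[[1]]$obs)
  allobs <- do.call(rbind, lapply(windows, `[[`, "obs"))
  alllab <- unlist(lapply(windows, `[[`, "labels"))
  stopifnot(sum(alllab) > d)  # enough labeled positions for a covariance

  fp_em <- weighted_gaussian(allobs[alllab, , drop = FALSE],
                             rep(1, sum(alllab)))

  old <- .Random.seed_save()
  set.seed(seed)
  gammas <- lapply(windows, function(w) {
    Tn <- nrow(w$obs)
    g <- matrix(stats::runif(Tn * S), Tn, S)
    g <- g / rowSums(g)
    g[w$labels, ] <- 0
    g[w$labels, footprint_state] <- 1
    g
  })
  # random-posterior averaging would hand every unlabeled state the global
  # mean (an exact EM fixed point); anchor their means at k-means centers
  # of the observations to break the symmetry
  anchor <- tryCatch(
    stats::kmeans(allobs, centers = S - 1L, nstart = 5L,
                  iter.max = 30L)$centers,
    error = function(e) allobs[sample.int(nrow(allobs), S - 1L), ,
                               drop = FALSE])
  .Random.seed_restore(old)

  m_step <- function(gammas, xis) {
    init <- Reduce(`+`, lapply(gammas, function(g) g[1, ]))
    init <- init / sum(init)
    trans <- Reduce(`+`, xis)
    trans <- trans / rowSums(trans)
    means <- matrix(0, S, d)
    covs <- vector("list", S)
    gall <- do.call(rbind, gammas)
    for (s in seq_len(S)) {
      if (s == footprint_state) {
        means[s, ] <- fp_em$mean
        covs[[s]] <- fp_em$cov
      } else {
        wg <- weighted_gaussian(allobs, gall[, s] + 1e-10)
        means[s, ] <- wg$mean
        covs[[s]] <- wg$cov
      }
    }
    footprint_hmm(init, trans, means, covs, footprint_state)
  }

  # pseudo-xi from outer products of consecutive random posteriors
  xis0 <- lapply(gammas, function(g) {
    Tn <- nrow(g)
    xi <- matrix(0, S, S)
    for (t in seq_len(Tn - 1L)) xi <- xi + g[t, ] %o% g[t + 1L, ]
    xi
  })
  model <- m_step(gammas, xis0)
  ai <- 0L
  for (s in seq_len(S)) {
    if (s == footprint_state) next
    ai <- ai + 1L
    model$means[s, ] <- anchor[ai, ]
  }

  llhist <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    es <- lapply(windows, function(w)
      forward_backward(model, w$obs, w$labels))
    ll <- sum(vapply(es, `[[`, numeric(1), "loglik"))
    llhist <- c(llhist, ll)
    model <- m_step(lapply(es, `[[`, "gamma"), lapply(es, `[[`, "xi"))
    if (iter > 1L &&
        abs(ll - llhist[iter - 1L]) <
        tol * (abs(llhist[iter - 1L]) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("Baum-Welch did not converge in ", max_iter,
            " iterations; returning best iterate")
  attr(model, "loglik") <- llhist
  attr(model, "converged") <- converged
  model
}

#' Viterbi decoding
#'
#' Maximum-joint-probability state path in log space; ties break toward the
#' lower state index.
#'
#' @param model A [footprint_hmm()].
#' @param obs Observation matrix (columns must match the model dimension).
#' @return Integer state path of length `nrow(obs)`.
#' @export
viterbi_decode <- function(model, obs) {
  obs <- as.matrix(obs)
  stopifnot(ncol(obs) == model$d)
  B <- emission_logdens(model, obs)
  Tn <- nrow(B)
  S <- model$S
  logtrans <- log(model$trans)
  delta <- log(model$init) + B[1, ]
  psi <- matrix(0L, Tn, S)
  if (Tn > 1) for (t in 2:Tn) {
    cand <- delta + logtrans  # cand[i, j]: from i into j
    best <- apply(cand, 2, which.max)  # which.max takes the first (lowest) index
    delta <- cand[cbind(best, seq_len(S))] + B[t, ]
    psi[t, ] <- best
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Convert a decoded state path into footprint intervals
#'
#' Maximal runs of the FOOTPRINT state become intervals; runs shorter than
#' `min_len` or longer than `max_len` are discarded.
#'
#' @param path Integer state path over `region`.
#' @param region [gregion()] the path covers.
#' @param model A [footprint_hmm()] (supplies the footprint state index), or
#'   an integer state index.
#' @param min_len,max_len Footprint length filters (defaults 5 and 50 bp).
#' @return `GRanges` of footprints.
#' @export
extract_footprints <- function(path, region, model, min_len = 5L,
                               max_len = 50L) {
  fp <- if (inherits(model, "footprint_hmm")) model$footprint_state
        else as.integer(model)
  r <- rle(path == fp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len & r$lengths <= max_len
  GenomicRanges::GRanges(
    rep(region$chrom, sum(keep)),
    IRanges::IRanges(starts[keep] + region$start - 1L,
                     ends[keep] + region$start - 1L))
}

#' Tag-count score of a candidate site
#'
#' Sum of the bias-corrected cleavage signal over the union of the footprint
#' interval and its motif-match window; used to rank predictions.
#'
#' @param start,end 1-based inclusive interval (already unioned with the
#'   motif window by the caller, or a bare footprint).
#' @param signal Numeric corrected-signal vector over `region`.
#' @param region [gregion()] the signal covers.
#' @return Numeric score (0 for an empty intersection with the region).
#' @export
tag_count_score <- function(start, end, signal, region) {
  lo <- pmax(start, region$start) - region$start + 1L
  hi <- pmin(end, region$end) - region$start + 1L
  mapply(function(a, b) if (a > b) 0 else sum(signal[a:b]), lo, hi)
}

#' Serialize / deserialize a footprint HMM as JSON
#'
#' @param model A [footprint_hmm()].
#' @param path JSON file path.
#' @export
write_hmm <- function(model, path) {
  jsonlite::write_json(
    list(S = model$S, d = model$d, init = model$init, trans = model$trans,
         means = model$means, covs = model$covs,
         footprint_state = model$footprint_state),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- if (is.list(x$covs)) {
    lapply(x$covs, function(m) matrix(as.numeric(m), x$d, x$d))
  } else {  # simplifyVector collapses equal-shaped matrices to an S x d x d array
    lapply(seq_len(x$S), function(s) matrix(as.numeric(x$covs[s, , ]), x$d, x$d))
  }
  footprint_hmm(as.numeric(x$init),
                matrix(as.numeric(x$trans), x$S, x$S),
                matrix(as.numeric(x$means), x$S, x$d),
                covs, x$footprint_state)
}
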