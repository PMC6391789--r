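# Sparse local inhomogeneous mixture (SLIM) position dependency models.
#
# A SLIM model assigns each word position j a mixture between an independent
# marginal distribution p(w_j) and pairwise conditionals p(w_j | w_l) on
# upstream positions l < j with j - l <= d:
#
#   p(w) = prod_j [ p(C_j=0) p(w_j) + p(C_j=1) sum_l p(R_lj) p(w_j | w_l) ]
#
# Marginals and conditionals are frequency estimates from the word corpus;
# the mixture priors p(C_j), p(R_lj) are fitted by maximizing the supervised
# posterior of corpus words against uniform random negative words
# (discriminative maximum supervised posterior principle). A PWM is the
# special case p(C_j = 0) = 1 at every position.

#' Construct a SLIM model from explicit parameters
#'
#' Mostly useful for tests and for deserialization; [fit_slim_corpus()] is
#' the estimator.
#'
#' @param k Word length.
#' @param d Maximum dependency distance (`j - l <= d`).
#' @param marginals `k x 4` matrix, rows summing to 1 (columns A,C,G,T).
#' @param conditionals Named list `"l_j"` of `4 x 4` matrices with rows
#'   `p(w_j | w_l = a)` summing to 1, for every admissible pair.
#' @param prior_c Length-`k` vector of `p(C_j = 1)`; position 1 must be 0.
#' @param prior_r List indexed by `j` of named vectors `p(R_lj)` over
#'   admissible `l`, each summing to 1 (empty for j = 1).
#' @return An object of class `slim_model`.
#' @export
slim_model <- function(k, d, marginals, conditionals, prior_c, prior_r) {
  stopifnot(nrow(marginals) == k, ncol(marginals) == 4L,
            all(abs(rowSums(marginals) - 1) < 1e-9),
            length(prior_c) == k, prior_c[1] == 0,
            all(prior_c >= 0 & prior_c <= 1))
  for (j in seq_len(k)) {
    ls <- admissible_l(j, d)
    if (length(ls) == 0L) next
    stopifnot(setequal(names(prior_r[[j]]), as.character(ls)),
              abs(sum(prior_r[[j]]) - 1) < 1e-9)
    for (l in ls) {
      cm <- conditionals[[pair_key(l, j)]]
      stopifnot(!is.null(cm), all(abs(rowSums(cm) - 1) < 1e-9))
    }
  }
  structure(list(k = as.integer(k), d = as.integer(d), marginals = marginals,
                 conditionals = conditionals, prior_c = prior_c,
                 prior_r = prior_r),
            class = "slim_model")
}

admissible_l <- function(j, d) seq.int(max(1L, j - d), j - 1L)[seq_len(max(0L, min(j - 1L, d)))]

pair_key <- function(l, j) paste0(l, "_", j)

#' Word probability under a SLIM model
#'
#' @param model A [slim_model()].
#' @param words Character vector of ACGT words of length `model$k`.
#' @return Numeric probabilities in `[0, 1]`; they sum to 1 over all `4^k`
#'   words for any valid model.
#' @export
slim_probability <- function(model, words) {
  if (!all(grepl("^[ACGT]+$", words)) || !all(nchar(words) == model$k))
    stop("words must be ACGT strings of length k")
  m <- word_matrix(words, model$k)
  p <- rep(1, length(words))
  for (j in seq_len(model$k)) {
    marg <- model$marginals[j, ][m[, j]]
    pc <- model$prior_c[j]
    if (pc == 0) {
      p <- p * marg
      next
    }
    cond <- rep(0, length(words))
    for (l in admissible_l(j, model$d)) {
      r <- model$prior_r[[j]][[as.character(l)]]
      cm <- model$conditionals[[pair_key(l, j)]]
      cond <- cond + r * cm[cbind(m[, l], m[, j])]
    }
    p <- p * ((1 - pc) * marg + pc * cond)
  }
  unname(p)
}

#' Fit a SLIM model to a word corpus
#'
#' Marginals and pairwise conditionals are (pseudocounted) corpus
#' frequencies. The mixture priors are fitted discriminatively: corpus words
#' are positives, uniformly drawn random words of the same size are
#' negatives, and the logistic log-likelihood of the class posterior
#' `sigma(log p(w) - log q(w))` (q uniform) is maximized over
#' logit/softmax-transformed priors by BFGS.
#'
#' @param words Character word multiset.
#' @param k Word length.
#' @param d Maximum dependency distance (`<= 5`).
#' @param seed Seed for the negative draw.
#' @param pseudocount Added to every marginal and conditional count cell.
#' @param maxit Maximum optimizer iterations.
#' @param tol Relative tolerance on the objective.
#' @param max_neg Cap on the number of negative words drawn.
#' @return A [slim_model()] with a `convergence` attribute (0 = converged).
#' @export
fit_slim_corpus <- function(words, k, d = 5L, seed = 1L, pseudocount = 1,
                            maxit = 500L, tol = 1e-6, max_neg = 50000L) {
  stopifnot(d <= 5L, length(words) > 0)
  tb <- word_counts(words)
  uw <- names(tb)
  wt_pos <- as.numeric(tb)
  marg <- position_probs(words, k, pseudocount)

  # conditionals from pairwise base counts
  mpos <- word_matrix(uw, k)
  conds <- list()
  pairs <- list()
  for (j in seq_len(k)) for (l in admissible_l(j, d)) {
    cnt <- matrix(pseudocount, 4, 4)
    for (i in seq_along(uw))
      cnt[mpos[i, l], mpos[i, j]] <- cnt[mpos[i, l], mpos[i, j]] + wt_pos[i]
    conds[[pair_key(l, j)]] <- cnt / rowSums(cnt)
    pairs[[length(pairs) + 1L]] <- c(l, j)
  }

  n_neg <- min(length(words), max_neg)
  old <- .Random.seed_save()
  set.seed(seed)
  neg <- apply(matrix(sample(DNA_BASES, n_neg * k, replace = TRUE),
                      ncol = k), 1, paste, collapse = "")
  .Random.seed_restore(old)
  tbn <- word_counts(neg)

  allw <- c(uw, names(tbn))
  wts <- c(wt_pos / sum(wt_pos), -as.numeric(tbn) / sum(tbn))
  # negative weight sign encodes the class; scale classes to equal mass
  mall <- word_matrix(allw, k)

  # Precompute per-position marginal lookups and per-pair conditional lookups
  M <- vapply(seq_len(k), function(j) marg[j, ][mall[, j]],
              numeric(length(allw)))
  CL <- lapply(pairs, function(p) {
    cm <- conds[[pair_key(p[1], p[2])]]
    cm[cbind(mall[, p[1]], mall[, p[2]])]
  })
  pairs_by_j <- lapply(seq_len(k), function(j)
    which(vapply(pairs, function(p) p[2] == j, logical(1))))

  free_j <- which(vapply(seq_len(k), function(j)
    length(admissible_l(j, d)) > 0, logical(1)))
  n_c <- length(free_j)
  n_a <- vapply(free_j, function(j) length(pairs_by_j[[j]]), integer(1))
  npar <- n_c + sum(n_a)

  unpack <- function(theta) {
    pc <- numeric(k)
    pc[free_j] <- stats::plogis(theta[seq_len(n_c)])
    rw <- vector("list", k)
    off <- n_c
    for (ii in seq_along(free_j)) {
      j <- free_j[ii]
      a <- theta[off + seq_len(n_a[ii])]
      off <- off + n_a[ii]
      e <- exp(a - max(a))
      rw[[j]] <- e / sum(e)
    }
    list(pc = pc, rw = rw)
  }

  # objective and gradient of the supervised posterior
  obj_grad <- function(theta) {
    par <- unpack(theta)
    logp <- rep(0, length(allw))
    Tmat <- matrix(0, length(allw), k)
    mj <- matrix(0, length(allw), k)
    for (j in seq_len(k)) {
      pj <- par$pc[j]
      Tj <- 0
      if (pj > 0 && length(pairs_by_j[[j]]) > 0) {
        ids <- pairs_by_j[[j]]
        for (ii in seq_along(ids))
          Tj <- Tj + par$rw[[j]][ii] * CL[[ids[ii]]]
      }
      Tmat[, j] <- Tj
      mj[, j] <- (1 - pj) * M[, j] + pj * Tj
      logp <- logp + log(mj[, j])
    }
    s <- logp + k * log(4)
    sig <- stats::plogis(s)
    y <- as.numeric(wts > 0)
    u <- abs(wts)
    f <- sum(u * (y * log(pmax(sig, 1e-300)) +
                    (1 - y) * log(pmax(1 - sig, 1e-300))))
    g <- u * (y - sig)
    grad <- numeric(npar)
    off <- n_c
    for (ii in seq_along(free_j)) {
      j <- free_j[ii]
      pj <- par$pc[j]
      grad[ii] <- sum(g * (Tmat[, j] - M[, j]) / mj[, j]) * pj * (1 - pj)
      ids <- pairs_by_j[[j]]
      for (a in seq_along(ids)) {
        grad[off + a] <- sum(g * pj * par$rw[[j]][a] *
                               (CL[[ids[a]]] - Tmat[, j]) / mj[, j])
      }
      off <- off + n_a[ii]
    }
    list(value = f, grad = grad)
  }

  theta0 <- rep(0, npar)
  theta0[seq_len(n_c)] <- -2  # start close to the PWM special case
  fit <- stats::optim(theta0,
                      fn = function(th) -obj_grad(th)$value,
                      gr = function(th) -obj_grad(th)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  if (fit$convergence != 0)
    warning("SLIM prior optimization did not converge; returning best iterate")
  par <- unpack(fit$par)
  prior_r <- vector("list", k)
  for (j in seq_len(k)) {
    ls <- admissible_l(j, d)
    if (length(ls) == 0L) { prior_r[[j]] <- numeric(0); next }
    v <- if (is.null(par$rw[[j]])) rep(1 / length(ls), length(ls)) else par$rw[[j]]
    names(v) <- as.character(ls)
    prior_r[[j]] <- v
  }
  out <- slim_model(k, d, marg, conds, par$pc, prior_r)
  attr(out, "convergence") <- fit$convergence
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit a SLIM bias model (observed vs background corpora)
#'
#' @param w_obs,w_exp Word multisets (see [collect_words()]).
#' @inheritParams fit_slim_corpus
#' @param force_pwm If `TRUE`, fix `p(C_j = 0) = 1` everywhere (degenerate
#'   PWM case; no prior optimization).
#' @return An object of class `c("slim_bias", "bias_model")` holding the two
#'   fitted [slim_model()]s.
#' @export
fit_slim <- function(w_obs, w_exp, k, d = 5L, seed = 1L, pseudocount = 1,
                     force_pwm = FALSE, maxit = 500L, tol = 1e-6) {
  fit1 <- function(w, sd) {
    if (force_pwm) {
      m <- fit_slim_corpus(w, k, d, seed = sd, pseudocount = pseudocount,
                           maxit = 0L, tol = tol)
      m$prior_c[] <- 0
      m
    } else {
      fit_slim_corpus(w, k, d, seed = sd, pseudocount = pseudocount,
                      maxit = maxit, tol = tol)
    }
  }
  structure(list(k = as.integer(k), d = as.integer(d),
                 obs = fit1(w_obs, seed), exp = fit1(w_exp, seed + 1L)),
            class = c("slim_bias", "bias_model"))
}

#' @export
bias_ratio.slim_bias <- function(model, words) {
  slim_probability(model$obs, words) / slim_probability(model$exp, words)
}

#' Serialize / deserialize a SLIM model as JSON
#'
#' @param model A [slim_model()].
#' @param path JSON file path.
#' @export
write_slim <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, d = model$d,
         marginals = model$marginals,
         conditionals = model$conditionals,
         prior_c = model$prior_c,
         prior_r = lapply(model$prior_r, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slim
#' @export
read_slim <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite round-trips matrices as nested row-major arrays that
  # simplifyVector restores to matrices
  conds <- lapply(x$conditionals, function(m) {
    m <- matrix(as.numeric(m), 4L, 4L)
    m
  })
  pr <- lapply(x$prior_r, function(v) {
    if (length(v) == 0) return(numeric(0))
    stats::setNames(unlist(v), names(v))
  })
  marg <- matrix(as.numeric(x$marginals), x$k, 4L)
  colnames(marg) <- DNA_BASES
  slim_model(x$k, x$d, marg, conds, as.numeric(x$prior_c), pr)
}
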