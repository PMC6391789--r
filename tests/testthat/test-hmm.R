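# brute-force Viterbi: enumerate all S^T paths
viterbi_brute <- function(model, obs) {
  B <- atacfoot:::emission_logdens(model, obs)
  S <- model$S
  Tn <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  best <- NULL
  bestlp <- -Inf
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(model$init[p[1]]) + B[1, p[1]]
    if (Tn > 1) for (t in 2:Tn)
      lp <- lp + log(model$trans[p[t - 1], p[t]]) + B[t, p[t]]
    if (lp > bestlp + 1e-12) {
      bestlp <- lp
      best <- p
    }
  }
  list(path = best, lp = bestlp)
}

path_logprob <- function(model, obs, p) {
  B <- atacfoot:::emission_logdens(model, obs)
  lp <- log(model$init[p[1]]) + B[1, p[1]]
  if (length(p) > 1) for (t in 2:length(p))
    lp <- lp + log(model$trans[p[t - 1], p[t]]) + B[t, p[t]]
  lp
}

random_hmm <- function(S, d) {
  init <- runif(S)
  init <- init / sum(init)
  tr <- matrix(runif(S * S), S)
  tr <- tr / rowSums(tr)
  means <- matrix(rnorm(S * d, sd = 2), S, d)
  covs <- lapply(seq_len(S), function(s) {
    A <- matrix(rnorm(d * d), d)
    crossprod(A) + diag(d) * 0.5
  })
  footprint_hmm(init, tr, means, covs, 1L)
}

test_that("Viterbi equals exhaustive path enumeration", {
  set.seed(60)
  for (i in 1:100) {
    S <- sample(2:3, 1)
    Tn <- sample(2:8, 1)
    d <- sample(1:2, 1)
    m <- random_hmm(S, d)
    obs <- matrix(rnorm(Tn * d), Tn, d)
    v <- viterbi_decode(m, obs)
    b <- viterbi_brute(m, obs)
    expect_equal(path_logprob(m, obs, v), b$lp, tolerance = 1e-9)
  }
})

test_that("Viterbi ties break toward the lower state index", {
  S <- 3
  m <- footprint_hmm(rep(1 / S, S), matrix(1 / S, S, S),
                     matrix(0, S, 1), rep(list(matrix(1)), S), 1L)
  obs <- matrix(rnorm(10), 10, 1)
  expect_equal(viterbi_decode(m, obs), rep(1L, 10))
  # single-state edge case: constant path
  m1 <- footprint_hmm(1, matrix(1, 1, 1), matrix(0, 1, 1),
                      list(matrix(1)), 1L)
  expect_equal(viterbi_decode(m1, obs), rep(1L, 10))
})

test_that("training windows carry the motif-centered label geometry", {
  set.seed(61)
  region <- gregion("chr1", 1, 5000)
  obs <- matrix(rnorm(5000 * 2), 5000, 2)
  mpbs <- GRanges("chr1", IRanges(c(1500, 3000, 4200), width = 11))
  chip <- GRanges("chr1", IRanges(c(1400, 2900), width = 300))  # supports 2
  w <- make_training_windows(mpbs, chip, obs, region, flank = 500L)
  expect_length(w, 2L)
  expect_equal(vapply(w, function(x) sum(x$labels), integer(1)), c(11L, 11L))
  expect_equal(nrow(w[[1]]$obs), 1001L)
  # labeled stretch sits at the window center
  expect_equal(which(w[[1]]$labels), 496:506)
  expect_error(make_training_windows(mpbs, GRanges(), obs, region),
               "no ChIP-supported")
})

test_that("semi-supervised training recovers a known generator", {
  set.seed(62)
  S <- 3
  tr <- matrix(c(0.90, 0.05, 0.05,
                 0.10, 0.85, 0.05,
                 0.15, 0.05, 0.80), S, byrow = TRUE)
  means <- matrix(c(-2, -2, 0, 0, 2.5, 2.5), S, byrow = TRUE)
  windows <- lapply(1:50, function(i) {
    Tn <- 120
    st <- integer(Tn)
    st[1] <- sample(seq_len(S), 1, prob = c(0.8, 0.1, 0.1))
    for (t in 2:Tn) st[t] <- sample(seq_len(S), 1, prob = tr[st[t - 1], ])
    obs <- t(vapply(st, function(s) rnorm(2, means[s, ], sqrt(0.3)),
                    numeric(2)))
    list(obs = obs, labels = st == 1L)
  })
  fit <- train_footprint_hmm(windows, S = 3, seed = 3, max_iter = 60)
  perm <- apply(as.matrix(dist(rbind(means, fit$means)))[1:3, 4:6], 1,
                which.min)
  expect_equal(sort(unname(perm)), 1:3)  # states distinct
  expect_lt(max(abs(fit$means[perm, ] - means)), 0.1)
  expect_lt(max(abs(fit$trans[perm, perm] - tr)), 0.1)
  # training objective is monotone non-decreasing
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-8 * abs(ll[-length(ll)])))
  # footprint emission comes from the labeled positions only
  lab_obs <- do.call(rbind, lapply(windows, function(w) w$obs[w$labels, ]))
  expect_equal(fit$means[1, ], colMeans(lab_obs), ignore_attr = TRUE)
  # same seed, same fit
  fit2 <- train_footprint_hmm(windows, S = 3, seed = 3, max_iter = 60)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$trans, fit2$trans)
})

test_that("separable two-cluster data decodes to the cluster assignment", {
  set.seed(63)
  st <- rep(c(TRUE, FALSE), each = 50)[sample(100)]
  obs <- matrix(ifelse(st, 10, -10) + rnorm(100, sd = 0.3), 100, 1)
  windows <- list(list(obs = obs, labels = st))
  fit <- suppressWarnings(
    train_footprint_hmm(windows, S = 2, seed = 1, max_iter = 40))
  dec <- viterbi_decode(fit, obs)
  expect_equal(dec == fit$footprint_state, st)
})

test_that("footprint extraction applies the length filters", {
  reg <- gregion("chr1", 1001, 1100)
  path <- rep(2L, 100)
  path[21:32] <- 1L   # 12-run: kept
  path[61:63] <- 1L   # 3-run: below min_len
  fp <- extract_footprints(path, reg, 1L)
  expect_length(fp, 1L)
  expect_equal(start(fp), 1021)
  expect_equal(end(fp), 1032)
  # an over-long run is discarded
  path2 <- rep(1L, 100)
  expect_length(extract_footprints(path2, reg, 1L, max_len = 50L), 0L)
})

test_that("tag count sums signal over the interval", {
  reg <- gregion("chr1", 1, 100)
  expect_equal(tag_count_score(10, 20, rep(0, 100), reg), 0)
  sig <- seq(0.1, 10, by = 0.1)
  expect_equal(tag_count_score(5, 8, sig, reg), sum(sig[5:8]))
  # monotone in the interval for non-negative signal
  expect_gte(tag_count_score(3, 12, sig, reg), tag_count_score(5, 8, sig, reg))
})

test_that("models survive a JSON round trip", {
  set.seed(64)
  m <- random_hmm(3, 2)
  path <- tempfile(fileext = ".json")
  write_hmm(m, path)
  m2 <- read_hmm(path)
  expect_equal(m2$init, m$init)
  expect_equal(m2$trans, m$trans, ignore_attr = TRUE)
  expect_equal(m2$means, m$means, ignore_attr = TRUE)
  expect_equal(m2$covs, m$covs, ignore_attr = TRUE)
  obs <- matrix(rnorm(20), 10, 2)
  expect_equal(viterbi_decode(m2, obs), viterbi_decode(m, obs))
})
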