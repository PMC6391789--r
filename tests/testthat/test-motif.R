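test_that("JASPAR PFM files parse into count matrices", {
  pfms <- read_jaspar(jaspar_fixture_path())
  expect_named(pfms, c("TOYA", "TOYB"))
  expect_equal(dim(pfms$TOYA), c(4L, 4L))
  expect_equal(unname(pfms$TOYA[, 1]), c(10, 0, 0, 0))
  expect_equal(unname(pfms$TOYA[, 4]), c(2, 2, 2, 4))
  expect_equal(dim(pfms$TOYB), c(4L, 2L))
})

test_that("PFM to PWM conversion is a background log-odds", {
  uni <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pfm_to_pwm(uni), matrix(0, 4, 3), ignore_attr = TRUE)
  # single-base column, pseudocount split by the background
  pfm <- matrix(c(10, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm, pseudocount = 0.1)
  expect_equal(unname(pwm["A", 1]), log2(((10 + 0.1 * 0.25) / 10.1) / 0.25))
  expect_equal(unname(pwm["T", 1]), log2(((0.025) / 10.1) / 0.25))
  # maximum achievable score is the sum of column maxima
  pfms <- read_jaspar(jaspar_fixture_path())
  p <- pfm_to_pwm(pfms$TOYA)
  expect_equal(max(vapply(all_words(4), function(w) pwm_score_word(p, w),
                          numeric(1))),
               sum(apply(p, 2, max)))
  expect_error(pfm_to_pwm(matrix(0, 4, 2)), "zero")
})

test_that("the DP score cutoff agrees with exhaustive enumeration", {
  set.seed(70)
  for (len in c(4L, 6L, 8L)) {
    pfm <- matrix(rpois(4 * len, 15) + 1, 4, len,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pfm_to_pwm(pfm)
    allw <- all_words(len)
    scores <- vapply(allw, function(w) pwm_score_word(pwm, w), numeric(1))
    # exhaustive-enumeration oracle on the same discretized score domain:
    # the DP convolution must reproduce the enumeration exactly
    istep <- 0.01 / len
    qs <- vapply(allw, function(w) {
      b <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
      sum(round(pwm / istep)[cbind(b, seq_along(b))])
    }, numeric(1))
    grid <- sort(unique(qs))
    for (fpr in c(0.05, 1e-2, 1e-3)) {
      cut <- threshold_at_fpr(pwm, fpr = fpr)
      tails <- vapply(grid, function(t) mean(qs >= t), numeric(1))
      # smallest integer score whose tail conforms (one above the last
      # non-conforming achievable score), or the maximum when none does
      brute <- if (all(tails > fpr)) max(grid)
               else if (all(tails <= fpr)) min(grid)
               else max(grid[tails > fpr]) + 1
      expect_equal(as.numeric(cut), brute * istep, tolerance = 1e-9)
      # the null tail respects the FPR bound up to one discretization step
      expect_lte(mean(scores >= as.numeric(cut) + 0.01), fpr)
    }
    # degenerate rates: everything / only the best word passes
    expect_lte(as.numeric(threshold_at_fpr(pwm, fpr = 1)) - min(scores),
               0.01)
    expect_lte(abs(as.numeric(threshold_at_fpr(pwm, fpr = 1e-12)) -
                     max(scores)), 0.01)
  }
})

test_that("scanning reports planted matches on both strands", {
  set.seed(71)
  g <- simulate_genome(10000, seed = 12)
  pfms <- read_jaspar(jaspar_fixture_path())
  pwm <- pfm_to_pwm(pfms$TOYA)
  cut <- threshold_at_fpr(pwm, fpr = 1e-3)
  consensus <- "ACGT"
  g2 <- plant_motif(g, consensus, c(2000L, 7000L))
  hits <- scan_motif(g2, pwm, cut, motif_name = "TOYA")
  fwd <- hits[strand(hits) == "+"]
  expect_true(all(c(2000L, 7000L) %in% start(fwd)))
  # reverse-complement planting appears on the minus strand
  g3 <- plant_motif(g, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(consensus))),
    4000L)
  hits3 <- scan_motif(g3, pwm, cut)
  expect_true(4000L %in% start(hits3[strand(hits3) == "-"]))
  # full brute-force sliding-window agreement
  seqchar <- as.character(g2[[1]])
  brute <- list()
  rc <- function(w) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w)))
  for (i in 1:(10000 - 3)) {
    w <- substr(seqchar, i, i + 3)
    if (pwm_score_word(pwm, w) >= cut)
      brute[[length(brute) + 1]] <- c(i, 1L)
    if (pwm_score_word(pwm, rc(w)) >= cut)
      brute[[length(brute) + 1]] <- c(i, 2L)
  }
  bm <- do.call(rbind, brute)
  got <- cbind(start(hits), ifelse(as.character(strand(hits)) == "+", 1L, 2L))
  expect_equal(got[order(got[, 1], got[, 2]), ],
               bm[order(bm[, 1], bm[, 2]), ], ignore_attr = TRUE)
})

test_that("genome-wide match counts follow the binomial expectation", {
  set.seed(72)
  L <- 200000L
  g <- simulate_genome(L, seed = 13)
  pfm <- matrix(rpois(4 * 8, 20) + 1, 4, 8,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  cut <- threshold_at_fpr(pwm, fpr = 1e-3)
  # exact per-window pass probability by enumeration of all 4^8 words
  scores <- vapply(all_words(8), function(w) pwm_score_word(pwm, w),
                   numeric(1))
  p <- mean(scores >= cut)
  hits <- scan_motif(g, pwm, cut)
  expected <- 2 * p * (L - 7)
  sdev <- sqrt(2 * (L - 7) * p * (1 - p))
  expect_lt(abs(length(hits) - expected), 3 * sdev)
})

test_that("scanning the reverse-complemented genome swaps strands only", {
  g <- simulate_genome(3000, seed = 14)
  pfms <- read_jaspar(jaspar_fixture_path())
  pwm <- pfm_to_pwm(pfms$TOYA)
  cut <- threshold_at_fpr(pwm, fpr = 5e-2)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  h1 <- scan_motif(g, pwm, cut)
  h2 <- scan_motif(grc, pwm, cut)
  L <- 3000L
  # a + match at s in g corresponds to a - match at L - (s+3) + 1 in rc(g)
  flip <- sort(L - end(h1) + 1L)
  expect_equal(sort(start(h2)), flip)
  expect_equal(table(strand(h1))[["+"]], table(strand(h2))[["-"]])
})

test_that("ChIP summit labels honor the inclusive distance boundary", {
  mpbs <- GRanges("chr1", IRanges(c(1000, 1101, 1102, 5000), width = 1))
  summits <- GRanges("chr1", IRanges(c(1001, 1001, 1001, 9000), width = 1))
  lab <- label_with_chipseq(mpbs, summits[1], radius = 100L)
  # centers at distance 1, 100, 101: inclusive boundary at 100
  expect_equal(lab$true_site, c(TRUE, TRUE, FALSE, FALSE))
  # brute-force distance check on a random layout
  set.seed(73)
  m <- GRanges("chr1", IRanges(sample(1:100000, 300), width = 11))
  s <- GRanges("chr1", IRanges(sample(1:100000, 20), width = 1))
  lab2 <- label_with_chipseq(m, s, radius = 100L)
  centers <- (start(m) + end(m)) %/% 2
  brute <- vapply(centers, function(cc) any(abs(cc - start(s)) <= 100),
                  logical(1))
  expect_equal(lab2$true_site, brute)
})
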