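test_that("word extraction follows the centered-word formula", {
  # offsets -floor(k/2) .. ceil(k/2)-1 around the event position
  expect_equal(extract_word("AACGTT", 3, 4), "AACG")
  expect_equal(extract_word("AACGTT", 3, 1), "C")
  expect_equal(extract_word("AACGTT", 3, 5), "AACGT")
  expect_true(is.na(extract_word("AACGTT", 1, 2)))    # left overhang
  expect_true(is.na(extract_word("AACGTT", 6, 4)))    # right overhang
  expect_true(is.na(extract_word("AANGTT", 3, 4)))    # non-ACGT
  # reverse-strand words are reverse-complemented
  expect_equal(extract_word("AACGTT", 3, 4, strand = "-"), "CGTT")
})

test_that("collect_words respects multiplicity and counts all peak positions", {
  g <- Biostrings::DNAStringSet("AAACGTACGTACGTAAAA")
  names(g) <- "chr1"
  reg <- gregion("chr1", 1, 18)
  counts <- rep(0, 18)
  counts[5] <- 3
  tr <- cleavage_track(reg, "+", "All", counts)
  peaks <- GRanges("chr1", IRanges(3, 16))
  w <- collect_words(list(tr), peaks, g, 4)
  expect_equal(w$obs, rep(extract_word(g, 5, 4, chrom = "chr1"), 3))
  # background: one word per peak position minus boundary skips (none here)
  expect_equal(length(w$exp), 14)
  brute <- vapply(3:16, function(p) extract_word(g, p, 4, chrom = "chr1"),
                  character(1))
  expect_equal(sort(w$exp), sort(brute))
})

test_that("k-mer bias matches hand arithmetic and brute force", {
  m <- estimate_kmer(c("AA", "AA", "AC", "AC"), c("AA", "AC", "AC", "AC"),
                     2, pseudocount = 0)
  expect_equal(bias_ratio(m, c("AA", "AC")), c(2, 2 / 3))
  # identical multisets give bias 1 for every present word
  w <- random_words(50, 3)
  m2 <- estimate_kmer(w, w, 3)
  expect_equal(bias_ratio(m2, unique(w)), rep(1, length(unique(w))))
  # uniform events on a uniform genome: all biases near 1
  set.seed(30)
  obs <- random_words(20000, 2)
  ex <- random_words(20000, 2)
  m3 <- estimate_kmer(obs, ex, 2)
  expect_true(all(abs(bias_ratio(m3, all_words(2)) - 1) < 0.15))
  # brute-force recomputation with the pseudocounted multinomial
  tb_o <- table(factor(obs, levels = all_words(2)))
  tb_e <- table(factor(ex, levels = all_words(2)))
  brute <- ((as.numeric(tb_o) + 1) / (20000 + 16)) /
    ((as.numeric(tb_e) + 1) / (20000 + 16))
  expect_equal(bias_ratio(m3, all_words(2)), brute)
})

test_that("PWM bias reduces to k-mer at k=1 and matches hand counts", {
  obs <- c("A", "C", "C")
  ex <- c("A", "A", "C", "G")
  expect_equal(bias_ratio(estimate_pwm(obs, ex), c("A", "C", "G", "T")),
               bias_ratio(estimate_kmer(obs, ex, 1), c("A", "C", "G", "T")))
  # hand counts without pseudocount: p(w1=A|obs)=1, p(w2=C)=p(w2=G)=0.5
  p <- estimate_pwm(c("AC", "AG"), c("AA", "CC", "GG", "TT"),
                    pseudocount = 0)
  expect_equal(unname(p$obs[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(p$obs[2, ]), c(0, 0.5, 0.5, 0))
  expect_equal(rowSums(p$obs), rep(1, 2), ignore_attr = TRUE)
  expect_equal(rowSums(p$exp), rep(1, 2), ignore_attr = TRUE)
})

test_that("track correction matches a brute-force evaluation of the formula", {
  set.seed(31)
  g <- simulate_genome(2000, seed = 9)
  reg <- gregion("chr1", 501, 550)
  y <- rpois(50, 2)
  tr <- cleavage_track(reg, "+", "All", y)
  m <- estimate_kmer(random_words(500, 4), random_words(500, 4), 4)
  for (mode in c("sum", "mean")) {
    x <- correct_track(tr, m, g, expected_counts_mode = mode)
    words <- extract_word(g, 501:550, 4, chrom = "chr1")
    b <- bias_ratio(m, words)
    brute <- numeric(50)
    for (i in 1:50) {
      win <- max(1, i - 25):min(50, i + 24)
      sy <- sum(y[win])
      yhat <- if (mode == "mean") sy / length(win) else sy
      bhat <- b[i] / sum(b[win])
      brute[i] <- (y[i] + 1) / (yhat * bhat + 1)
    }
    expect_equal(x, brute)
    expect_true(all(x > 0))
  }
})

test_that("correction is scale-free in the bias and neutral for flat signal", {
  g <- simulate_genome(2000, seed = 9)
  reg <- gregion("chr1", 501, 600)
  zero <- cleavage_track(reg, "+", "All", rep(0, 100))
  expect_equal(correct_track(zero, NULL, g), rep(1, 100))
  set.seed(32)
  y <- rpois(100, 3)
  tr <- cleavage_track(reg, "+", "All", y)
  m <- estimate_kmer(random_words(2000, 4), random_words(2000, 4), 4,
                     pseudocount = 0)
  x1 <- correct_track(tr, m, g)
  m_scaled <- m
  m_scaled$obs <- m$obs * 7  # with no pseudocount this scales every b(w) by 7
  expect_equal(bias_ratio(m_scaled, "ACGT"), 7 * bias_ratio(m, "ACGT"))
  x2 <- correct_track(tr, m_scaled, g)
  expect_equal(x1, x2)
})

test_that("bias correction lowers the dispersion of a biased, footprint-free track", {
  g <- simulate_genome(50000, seed = 11)
  peaks <- GRanges("chr1", IRanges(2001, 48000))
  bias <- simulate_bias_table(4, sd = 1.2, seed = 3)
  lib <- simulate_library(g, 40000, peaks, bias = bias, seed = 21)
  reg <- gregion("chr1", 2001, 48000)
  trp <- build_signal(lib$fragments, reg, "+", "All", chrom_len = 50000)
  trm <- build_signal(lib$fragments, reg, "-", "All", chrom_len = 50000)
  w <- collect_words(list(trp, trm), peaks, g, 4)
  km <- estimate_kmer(w$obs, w$exp, 4)
  # estimated bias tracks the planted table
  expect_gt(cor(bias_ratio(km, names(bias)), bias, method = "spearman"),
            0.9)
  cv <- function(v) sd(v) / mean(v)
  corrected <- correct_track(trp, km, g)
  uncorrected <- correct_track(trp, NULL, g)
  expect_lt(cv(corrected), cv(uncorrected))
  expect_lt(cv(corrected), cv(trp$counts))
})

test_that("bias tables serialize to TSV with consistent probabilities", {
  m <- estimate_kmer(random_words(200, 3), random_words(200, 3), 3)
  path <- tempfile(fileext = ".tsv")
  write_bias_table(m, path)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  expect_true(all(c("word", "obs_prob", "exp_prob", "bias") %in% names(df)))
  expect_equal(df$bias, df$obs_prob / df$exp_prob)
  expect_equal(df$bias, bias_ratio(m, df$word))
})
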