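test_that("cleavage positions follow the protocol shift", {
  expect_equal(cleavage_position(100L, "+", "atac"), 104L)
  expect_equal(cleavage_position(100L, "-", "atac"), 95L)
  expect_equal(cleavage_position(100L, "+", "dnase"), 100L)
  expect_equal(cleavage_position(100L, "-", "dnase"), 100L)
  # configurable shift pair
  expect_equal(cleavage_position(50L, "+", "atac", shift = c(0L, 0L)), 50L)
})

test_that("fragment classification matches interval arithmetic exhaustively", {
  sch <- fragment_scheme()
  expect_equal(classify_fragment(145L), "Nfr")
  expect_equal(classify_fragment(146L), "1N")
  expect_equal(classify_fragment(307L), "1N")
  expect_equal(classify_fragment(308L), "+2N")
  lens <- 1:2000
  cls <- classify_fragment(lens, sch)
  direct <- ifelse(lens > 0 & lens <= 145, "Nfr",
                   ifelse(lens <= 307, "1N", "+2N"))
  expect_identical(cls, direct)
  # All contains every length; +1N is the union of 1N and +2N; the three
  # partition classes are disjoint and exhaustive
  expect_true(all(in_fragment_class(lens, "All", sch)))
  expect_identical(in_fragment_class(lens, "+1N", sch),
                   in_fragment_class(lens, "1N", sch) |
                     in_fragment_class(lens, "+2N", sch))
  membership <- cbind(in_fragment_class(lens, "Nfr", sch),
                      in_fragment_class(lens, "1N", sch),
                      in_fragment_class(lens, "+2N", sch))
  expect_true(all(rowSums(membership) == 1))
})

test_that("boundary estimation finds tri-modal minima and falls back", {
  h <- tri_modal_histogram()
  sch <- estimate_boundaries(h)
  expect_lte(abs(sch$nfr_upper - 145L), 10L)
  expect_lte(abs(sch$mono_upper - 307L), 10L)
  # the estimate is the exhaustive argmin of the smoothed histogram
  sm <- as.numeric(stats::filter(c(rep(0, 5), h, rep(0, 5)),
                                 rep(1 / 11, 11), sides = 2))[5 + 1:1000]
  m1 <- 60 + which.min(sm[60:200]) - 1L
  m2 <- 200 + which.min(sm[200:400]) - 1L
  expect_equal(sch$nfr_upper, m1)
  expect_equal(sch$mono_upper, m2)

  unimodal <- round(1e5 * dnorm(1:1000, 100, 10))
  expect_warning(s2 <- estimate_boundaries(unimodal), "default")
  expect_equal(c(s2$nfr_upper, s2$mono_upper), c(145L, 307L))
  delta <- replace(rep(0L, 1000), 100, 50L)
  expect_warning(s3 <- estimate_boundaries(delta), "default")
  expect_equal(c(s3$nfr_upper, s3$mono_upper), c(145L, 307L))
  expect_error(estimate_boundaries(integer(0)), "empty")
})

test_that("build_signal shifts, filters by class, and matches brute force", {
  reg <- gregion("chr1", 1, 100)
  fr <- data.frame(chrom = "chr1", start = c(1L, 1L), end = c(80L, 80L),
                   length = c(80L, 80L))
  tr <- build_signal(fr, reg, "+", "All")
  expect_equal(tr$counts[5], 2)  # 5' ends at 1 shift to 5
  expect_equal(sum(tr$counts), 2)
  # a 150 bp fragment contributes nothing under Nfr
  fr150 <- data.frame(chrom = "chr1", start = 10L, end = 159L, length = 150L)
  expect_equal(sum(build_signal(fr150, reg, "+", "Nfr")$counts), 0)

  set.seed(101)
  n <- 1000
  starts <- sample(30:1800, n, replace = TRUE)
  lens <- sample(20:400, n, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = starts,
                   end = starts + lens - 1L, length = lens)
  reg <- gregion("chr1", 200, 1500)
  for (strand in c("+", "-")) for (cls in c("All", "Nfr", "+1N")) {
    tr <- build_signal(fr, reg, strand, cls)
    brute <- numeric(length(reg))
    for (i in seq_len(n)) {
      if (!in_fragment_class(fr$length[i], cls)) next
      p <- if (strand == "+") fr$start[i] + 4L else fr$end[i] - 5L
      off <- p - reg$start + 1L
      if (off >= 1 && off <= length(reg)) brute[off] <- brute[off] + 1
    }
    expect_equal(tr$counts, brute)
  }
})

test_that("class decomposition conserves total cleavage events", {
  set.seed(7)
  n <- 500
  starts <- sample(100:5000, n, replace = TRUE)
  lens <- sample(20:600, n, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = starts,
                   end = starts + lens - 1L, length = lens)
  reg <- gregion("chr1", 1, 6000)  # contains every shifted event
  for (strand in c("+", "-")) {
    all_tr <- build_signal(fr, reg, strand, "All")
    parts <- lapply(c("Nfr", "1N", "+2N"), function(cl)
      build_signal(fr, reg, strand, cl)$counts)
    expect_equal(Reduce(`+`, parts), all_tr$counts)
  }
  # DNase protocol leaves positions unshifted; total mass is preserved by
  # the ATAC shift when nothing falls off-chromosome
  dn <- build_signal(fr, reg, "+", "All", protocol = "dnase")
  expect_equal(sum(dn$counts), n)
  expect_equal(sum(build_signal(fr, reg, "+", "All")$counts), n)
})

test_that("BAM round trip preserves simulated fragments", {
  g <- simulate_genome(20000, seed = 2)
  peaks <- GRanges("chr1", IRanges(2001, 18000))
  lib <- simulate_library(g, 500, peaks, seed = 4)
  bam <- write_bam_fragments(lib$fragments, g, tempfile())
  got <- read_fragments(bam)
  want <- unique(lib$fragments[, c("chrom", "start", "end", "length")])
  want <- want[order(want$start, want$end), ]
  got <- got[order(got$start, got$end), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$length, want$length)
})
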