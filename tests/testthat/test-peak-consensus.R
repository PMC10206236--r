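# Fixed-width standardization, blacklist filtering, score-per-million,
# iterative overlap removal, reproducible-set construction, and fragment
# counting — each checked against quadratic brute-force oracles.

test_that("summit standardization yields 501 bp peaks and drops edge summits", {
  g <- toy_genome(c(chr1 = 1e6))
  s <- data.frame(chrom = "chr1", summit = c(10000, 100, 999900),
                  score = c(5, 5, 5))
  pk <- standardize_peaks(s, g)
  expect_identical(nrow(pk), 1L) # summits 100 and 999900 run off the ends
  expect_equal(pk$start, 9750)
  expect_equal(pk$end, 10251)
  expect_equal(pk$end - pk$start, 501)

  set.seed(1)
  many <- data.frame(chrom = "chr1",
                     summit = floor(runif(1000, 1000, 999000)), score = 1)
  std <- standardize_peaks(many, g)
  expect_identical(nrow(std), 1000L)
  expect_true(all(std$end - std$start == 501))
  expect_error(standardize_peaks(data.frame(chrom = "chrQ", summit = 1,
                                            score = 1), g), "unknown")
})

test_that("blacklist filtering uses half-open >= 1 bp overlap semantics", {
  pk <- data.frame(chrom = "chr1", start = c(100, 100, 500),
                   end = c(200, 200, 700), score = 1)
  expect_identical(filter_blacklist(pk, NULL), pk)
  expect_identical(
    filter_blacklist(pk, data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0))), pk)
  # abutting interval (blacklist starts exactly at peak end) keeps the peak
  bl_abut <- data.frame(chrom = "chr1", start = 200, end = 300)
  expect_identical(nrow(filter_blacklist(pk, bl_abut)), 3L)
  # one bp of overlap removes it
  bl_hit <- data.frame(chrom = "chr1", start = 199, end = 300)
  expect_identical(nrow(filter_blacklist(pk, bl_hit)), 1L)

  g <- toy_genome()
  for (s in 1:10) {
    peaks <- rand_std_peaks(60, g, seed = s)
    bl <- rand_intervals(15, g, seed = 1000 + s)
    kept <- filter_blacklist(peaks, bl)
    expect_identical(kept$name, peaks$name[!bf_overlaps_any(peaks, bl)])
  }
})

test_that("score per million is exact, sums to 1e6, and is scale invariant", {
  pk <- data.frame(chrom = "chr1", start = c(0, 600, 1200),
                   end = c(501, 1101, 1701), score = c(2, 3, 5))
  spm <- score_per_million(pk)
  expect_equal(spm$spm, c(2e5, 3e5, 5e5))
  one <- score_per_million(pk[1, ])
  expect_equal(one$spm, 1e6)

  set.seed(4)
  pk2 <- rand_std_peaks(50, toy_genome(), seed = 4)
  a <- score_per_million(pk2)
  expect_equal(sum(a$spm), 1e6, tolerance = 1e-9)
  pk2$score <- pk2$score * 737.3
  expect_equal(score_per_million(pk2)$spm, a$spm, tolerance = 1e-12)
  pk_bad <- pk
  pk_bad$score[1] <- 0
  expect_error(score_per_million(pk_bad), "positive")
})

test_that("iterative overlap removal: chain, ties, order independence, oracle", {
  # A(10) overlaps B(8), B overlaps C(6), A does not overlap C -> keep A, C
  chain <- data.frame(chrom = "chr1", start = c(0, 80, 160),
                      end = c(100, 180, 260), score = c(10, 8, 6),
                      name = c("A", "B", "C"))
  red <- iterative_overlap_reduce(chain, "score")
  expect_identical(red$name, c("A", "C"))

  # identical intervals, tied scores: exactly one kept
  tie <- data.frame(chrom = "chr1", start = c(10, 10), end = c(110, 110),
                    score = c(5, 5), name = c("x", "y"))
  expect_identical(nrow(iterative_overlap_reduce(tie, "score")), 1L)

  disjoint <- data.frame(chrom = "chr1", start = c(0, 1000),
                         end = c(501, 1501), score = c(1, 2),
                         name = c("d1", "d2"))
  expect_identical(iterative_overlap_reduce(disjoint, "score")$name,
                   c("d1", "d2"))

  g <- toy_genome(c(chr1 = 3e4, chr2 = 2e4))
  for (s in 1:20) {
    peaks <- rand_std_peaks(40, g, seed = s) # dense -> many overlaps
    red1 <- iterative_overlap_reduce(peaks, "score")
    bf <- bf_iterative_reduce(peaks, "score")
    expect_identical(red1$name, bf$name)
    # order independence
    shuf <- peaks[sample(nrow(peaks)), ]
    expect_identical(iterative_overlap_reduce(shuf, "score")$name, red1$name)
    # every kept peak overlaps only itself within the kept set
    expect_true(all(vapply(seq_len(nrow(red1)), function(i) {
      sum(red1$chrom == red1$chrom[i] & red1$start < red1$end[i] &
            red1$end > red1$start[i]) == 1
    }, logical(1))))
  }
})

test_that("reproducible set: hand fixture, thresholds, chrY, invariants", {
  mk <- function(start, spm, chrom = "chr1") {
    data.frame(chrom = chrom, start = start, end = start + 501,
               summit = start + 250, score = spm, spm = spm,
               stringsAsFactors = FALSE)
  }
  # archetype near 1000 in all three samples; private peaks elsewhere
  s1 <- rbind(mk(1000, 10), mk(5000, 9))
  s2 <- rbind(mk(1010, 8), mk(9000, 9))
  s3 <- rbind(mk(990, 7), mk(13000, 9))
  cons <- build_reproducible_set(list(a = s1, b = s2, c = s3))
  expect_identical(nrow(cons), 1L)
  expect_equal(cons$start, 1000) # the spm-10 representative wins
  expect_identical(cons$support, 3L)

  # single sample: support < 2 everywhere -> empty consensus
  expect_identical(nrow(build_reproducible_set(list(a = s1))), 0L)

  # spm 4.9 winner in a 2-sample archetype is excluded at the 5 threshold
  t1 <- mk(1000, 4.9)
  t2 <- mk(1010, 4.5)
  expect_identical(nrow(build_reproducible_set(list(a = t1, b = t2))), 0L)

  # chrY peaks are removed even with full support
  y1 <- mk(1000, 50, chrom = "chrY")
  y2 <- mk(1005, 40, chrom = "chrY")
  expect_identical(nrow(build_reproducible_set(list(a = y1, b = y2))), 0L)

  expect_error(build_reproducible_set(list(a = data.frame(
    chrom = "chr1", start = 1, end = 502, score = 1))), "spm")
})

test_that("reproducible set equals the brute-force oracle on random fixtures", {
  g <- toy_genome(c(chr1 = 5e4, chr2 = 3e4, chrY = 2e4))
  for (s in 1:15) {
    samples <- lapply(1:3, function(i) {
      pk <- rand_std_peaks(25, g, seed = s * 10 + i)
      pk <- iterative_overlap_reduce(pk, "score")
      score_per_million(pk)
    })
    names(samples) <- c("s1", "s2", "s3")
    cons <- build_reproducible_set(samples)
    bf <- bf_consensus(samples)
    expect_equal(cons$start, bf$start)
    expect_equal(cons$spm, bf$spm)
    expect_identical(cons$support, as.integer(bf$support))
    # invariants: disjoint, spm >= 5, support >= 2, no chrY, width 501
    expect_true(all(cons$spm >= 5))
    expect_true(all(cons$support >= 2))
    expect_false(any(cons$chrom == "chrY"))
    expect_true(all(cons$end - cons$start == 501))
  }
})

test_that("fragment counting matches conventions and the all-pairs oracle", {
  pk <- data.frame(chrom = "chr1", start = c(1000, 1501), end = c(1501, 2002),
                   name = c("pA", "pB"), stringsAsFactors = FALSE)
  frags <- list(
    s1 = data.frame(chrom = "chr1", start = c(1100, 1450), end = c(1200, 1600))
  )
  cm <- count_fragments(frags, pk)
  # fragment 1 inside pA only; fragment 2 spans the pA|pB junction -> both
  expect_identical(cm$counts["pA", "s1"], 2L)
  expect_identical(cm$counts["pB", "s1"], 1L)
  expect_equal(unname(cm$lib_sizes), 3)

  g <- toy_genome()
  for (s in 1:8) {
    peaks <- iterative_overlap_reduce(rand_std_peaks(30, g, seed = s), "score")
    fr <- list(f1 = rand_intervals(80, g, seed = 100 + s, min_w = 50,
                                   max_w = 400),
               f2 = rand_intervals(60, g, seed = 200 + s, min_w = 50,
                                   max_w = 400))
    cm2 <- count_fragments(fr, peaks)
    expect_identical(unname(cm2$counts), unname(bf_count_fragments(fr, peaks)))
  }
})
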