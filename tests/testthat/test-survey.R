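test_that("coverage histogram bins counts of three or more", {
  h <- coverage_histogram(c(3L, 3L, 4L))
  expect_identical(h$coverage, c(3L, 4L))
  expect_equal(h$prob, c(2 / 3, 1 / 3))
  expect_equal(sum(h$prob), 1)
  expect_identical(nrow(coverage_histogram(c(1L, 2L))), 0L)
  ## histogram mean equals the sample mean of retained counts
  set.seed(61)
  x <- sample_tag_counts(5000, 10, 1)
  h2 <- coverage_histogram(x)
  expect_equal(sum(h2$coverage * h2$prob), mean(x[x >= 3]))
})

test_that("window statistics tile the genome and conserve mapped reads", {
  ref <- c(chr1 = paste0(strrep("G", 500), strrep("C", 500),
                         strrep("A", 1000), strrep("N", 100)))
  reps <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  aln <- data.table::data.table(
    sequence = strrep("A", 33), mapped = TRUE, chrom = "chr1",
    pos = c(10L, 900L, 1500L), strand = "+", n_mismatches = 0L,
    n_best_hits = 1L, mapping_quality = 40L, read_count = c(5L, 2L, 7L))
  ws <- window_stats(ref, reps, aln, window = 1000L)
  expect_identical(ws$start, c(0L, 1000L, 2000L))
  expect_equal(ws$repetitive_fraction[1], 1.0)   # fully repeat-masked window
  expect_equal(ws$gc_fraction[1], 1.0)           # all-G/C window
  expect_equal(ws$gc_fraction[2], 0.0)
  expect_true(is.na(ws$gc_fraction[3]))          # all-N window: no denominator
  expect_equal(ws$read_count, c(7, 7, 0))        # leftmost-coordinate binning
  expect_equal(sum(ws$read_count), sum(aln$read_count))

  ## conservation on a full study
  res <- small_clean_run()
  ws2 <- window_stats(res$sim$reference, res$sim$repeats, res$alignments)
  mapped <- res$alignments[res$alignments$mapped == TRUE, ]
  expect_equal(sum(ws2$read_count), sum(mapped$read_count))
})

test_that("pearson_r matches the closed form and an independent summation", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-12)
  expect_true(is.na(pearson_r(rep(1, 5), 1:5)))
  expect_error(pearson_r(1:3, 1:4), "equal length")

  ## independent direct-summation implementation
  direct_r <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / n
    den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
    num / den
  }
  set.seed(67)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(pearson_r(x, y), direct_r(x, y), tolerance = 1e-12)
  }
})

test_that("high-coverage tags are repeat-enriched when repeats pile up", {
  aln <- data.table::data.table(
    sequence = strrep("A", 33), mapped = TRUE, chrom = "chr1",
    pos = c(0L, 100L, 500L), strand = "+", n_mismatches = 0L,
    n_best_hits = 1L, mapping_quality = 40L,
    read_count = c(500L, 10L, 300L))
  reps <- data.frame(chrom = "chr1", start = 0L, end = 150L)
  enr <- high_coverage_repeat_enrichment(aln, reps)
  expect_equal(enr$pct_repetitive_above, 50)   # one of two >200 in repeats
  expect_equal(enr$pct_repetitive_below, 100)
  enr0 <- high_coverage_repeat_enrichment(aln, NULL)
  expect_equal(enr0$pct_repetitive_above, 0)
  expect_equal(enr0$pct_repetitive_below, 0)

  ## directional property on a full study with repeat-driven pile-up
  res <- demo_run()
  e <- res$survey$enrichment
  expect_gt(e$pct_repetitive_above, e$pct_repetitive_below)
})

test_that("SNP read-position distribution counts supporting pairs", {
  set.seed(71)
  ref <- c(chr1 = rand_dna(300))
  tag <- substr(ref[[1]], 101, 133)
  v <- strsplit(tag, "")[[1]]
  alt_base <- setdiff(c("A", "C", "G", "T"), v[1])[1]
  v[1] <- alt_base
  aln <- data.table::data.table(
    sequence = paste(v, collapse = ""), mapped = TRUE, chrom = "chr1",
    pos = 100L, strand = "+", n_mismatches = 1L, n_best_hits = 1L,
    mapping_quality = 40L, read_count = 3L,
    quality = strrep("?", 33))
  cand <- data.table::data.table(chrom = "chr1", pos = 100L,
                                 ref = substr(ref[[1]], 101, 101),
                                 alt = alt_base)
  d <- snp_read_position_distribution(cand, aln)
  expect_identical(unname(d[1]), 3L)      # offset 1, weighted by read count
  expect_identical(sum(d), 3L)
  ## empty inputs give all-zero bins
  expect_identical(sum(snp_read_position_distribution(cand[0, ], aln)), 0L)

  ## minus-strand support reports sequencing-orientation positions
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste(v, collapse = ""))))
  aln_m <- data.table::copy(aln)[, `:=`(sequence = rc, strand = "-",
                                        read_count = 2L)]
  dm <- snp_read_position_distribution(cand, aln_m)
  expect_identical(unname(dm[33]), 2L)    # first ref base = last read base
})

test_that("read-position distribution is roughly uniform for spiked SNPs", {
  res <- demo_run()
  ## one vote per (candidate, supporting unique tag): duplicate read counts
  ## would overweight single positions and distort the sampling model
  aln1 <- data.table::copy(res$alignments)[, read_count := 1L]
  d <- snp_read_position_distribution(res$lenient, aln1)
  expect_gt(sum(d), 50L)
  ## coarse thirds of the read; spiked SNPs have no positional preference
  thirds <- c(sum(d[1:11]), sum(d[12:22]), sum(d[23:33]))
  p <- suppressWarnings(stats::chisq.test(thirds)$p.value)
  expect_gt(p, 0.01)
})

test_that("validation-rate arithmetic rounds half-up at the asked precision", {
  expect_equal(rate(52, 61)$rate_pct, 85)
  expect_equal(rate(113, 171, 1)$rate_pct, 66.1)
  expect_equal(rate(164, 232)$rate_pct, 71)   # the recomputed overall rate
  expect_equal(rate(0, 10)$rate_pct, 0)
  expect_error(rate(1, 0), "positive")
  expect_error(rate(5, 3), "n_positive")
})

test_that("clone-hit classification partitions and sums to one hundred", {
  cl <- classify_clone_hits(74, 27, 53, n_good = 154)
  expect_equal(cl$rate_pct, c(48.1, 17.5, 34.4))
  expect_equal(sum(cl$n), 154)
  expect_lt(abs(sum(cl$rate_pct) - 100), 0.2)

  cl2 <- classify_clone_hits(hit_counts = c(rep(1L, 10)))
  expect_equal(cl2$rate_pct, c(100, 0, 0))
  expect_error(classify_clone_hits(10, 5, 5, n_good = 19), "partition")
})
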