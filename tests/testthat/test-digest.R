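test_that("enzyme specs validate IUPAC codes, palindromicity and cut offsets", {
  e <- enzyme_spec("CviRI", "TGCA", 2)
  expect_s3_class(e, "enzyme_spec")
  expect_identical(e$recognition, "TGCA")
  expect_error(enzyme_spec("BadEnz", "GGXC", 2), "IUPAC")
  expect_error(enzyme_spec("Bad2", "GAAT", 2), "palindromic")
  expect_error(enzyme_spec("Bad3", "TGCA", 5), "cut_offset")
})

test_that("the enzyme table loader parses rows and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_offset",
               "CviRI\tTGCA\t2", "HaeIII\tGGCC\t2"), path)
  specs <- load_enzyme_table(path)
  expect_named(specs, c("CviRI", "HaeIII"))
  expect_identical(specs$CviRI$cut_offset, 2L)

  writeLines(c("name\trecognition\tcut_offset",
               "CviRI\tTGCA\t2", "CviRI\tTGCA\t2"), path)
  expect_error(load_enzyme_table(path), "duplicate")

  writeLines(c("name\trecognition\tcut_offset", "BadEnz\tGGXC\t2"), path)
  expect_error(load_enzyme_table(path), "row 1")

  panel <- default_enzyme_panel()
  expect_length(panel, 7L)
  expect_setequal(names(panel),
                  c("AccII", "HaeIII", "RsaI", "DpnI", "AluI",
                    "CviRI", "CviJI"))
})

test_that("cut-position scanning handles single, repeated and absent sites", {
  cviri <- enzyme_spec("CviRI", "TGCA", 2)
  expect_identical(scan_cut_positions("AAATGCAAAA", cviri), 5L)
  expect_identical(scan_cut_positions("TGCATGCA", cviri), c(2L, 6L))
  expect_identical(scan_cut_positions("AAAAAAAA", cviri), integer(0))
  ## N never matches any IUPAC code
  expect_identical(scan_cut_positions("AATGNAAA", cviri), integer(0))
  expect_identical(scan_cut_positions("AANGCAAA", cviri), integer(0))
  ## tandem sites each produce a cut
  alui <- enzyme_spec("AluI", "AGCT", 2)
  s <- strrep("AGCT", 1000)
  expect_identical(scan_cut_positions(s, alui), oracle_scan(s, alui))
  expect_length(scan_cut_positions(s, alui), 1000L)
})

test_that("cut scanning agrees with the regex oracle for the whole panel", {
  set.seed(42)
  panel <- default_enzyme_panel()
  for (i in 1:3) {
    s <- rand_dna(20000)
    for (e in panel) {
      expect_identical(scan_cut_positions(s, e), oracle_scan(s, e),
                       info = e$name)
    }
  }
})

test_that("digestion partitions each chromosome exactly", {
  cviri <- enzyme_spec("CviRI", "TGCA", 2)
  f <- digest(c(chr1 = "AAATGCAAAA"), cviri)
  expect_identical(f$sequence, c("AAATG", "CAAAA"))
  expect_identical(f$length, c(5L, 5L))
  expect_true(all(f$terminal))

  f0 <- digest(c(chr1 = "AAAAAAAA"), cviri)
  expect_identical(nrow(f0), 1L)
  expect_true(f0$terminal)
  expect_identical(f0$length, 8L)

  set.seed(9)
  g <- c(chrA = rand_dna(100000), chrB = rand_dna(50000))
  fr <- digest(g, cviri, sequences = FALSE)
  for (ch in names(g)) {
    x <- fr[fr$chrom == ch, ]
    expect_identical(sum(x$length), nchar(g[[ch]]))
    expect_identical(x$start, c(0L, head(x$end, -1L)))  # sorted, gap-free
  }
  ## concatenating sequences reconstructs the chromosome
  fs <- digest(g["chrB"], cviri)
  expect_identical(paste(fs$sequence, collapse = ""), unname(g[["chrB"]]))
})

test_that("size selection keeps the inclusive 70-200 window and is idempotent", {
  cviri <- enzyme_spec("CviRI", "TGCA", 2)
  set.seed(3)
  fr <- digest(c(chr = rand_dna(50000)), cviri, sequences = FALSE)
  sel <- size_select(fr, 70, 200)
  expect_true(all(sel$length >= 70 & sel$length <= 200))
  expect_identical(sel$fragment_id,
                   fr$fragment_id[fr$length >= 70 & fr$length <= 200])
  expect_true(all(sel$selected))
  expect_identical(size_select(sel, 70, 200)$fragment_id, sel$fragment_id)
  ## explicit boundary behaviour
  fb <- data.table::data.table(
    fragment_id = letters[1:4], chrom = "c", start = c(0L, 100L, 200L, 500L),
    end = c(50L, 170L, 400L, 701L), length = c(50L, 70L, 200L, 201L),
    terminal = FALSE, selected = FALSE)
  expect_identical(size_select(fb, 70, 200)$length, c(70L, 200L))
  expect_identical(nrow(size_select(fb[0, ], 70, 200)), 0L)
  expect_error(size_select(fb, 200, 70), "exceeds")
})

test_that("terminal tags have 33-bp footprints inside their fragment", {
  fr <- data.table::data.table(
    fragment_id = c("f70", "f33", "f200"), chrom = "chr1",
    start = c(0L, 500L, 1000L), end = c(70L, 533L, 1200L),
    length = c(70L, 33L, 200L), terminal = FALSE, selected = TRUE)
  tg <- extract_tags(fr)
  t70 <- tg[tg$fragment_id == "f70", ]
  expect_identical(sort(t70$start), c(0L, 37L))
  expect_identical(sort(t70$end), c(33L, 70L))
  t33 <- tg[tg$fragment_id == "f33", ]
  expect_identical(nrow(t33), 1L)
  expect_true(t33$collapsed)
  t200 <- tg[tg$fragment_id == "f200", ]
  expect_identical(sort(t200$start), c(1000L, 1167L))
  expect_identical(sort(t200$end), c(1033L, 1200L))
  for (i in seq_len(nrow(tg))) {
    f <- fr[fr$fragment_id == tg$fragment_id[i], ]
    expect_true(tg$start[i] >= f$start && tg$end[i] <= f$end)
  }
})

test_that("tag repeat fractions follow interval arithmetic", {
  tg <- data.table::data.table(chrom = "c", start = 0L, end = 33L)
  expect_equal(tag_repeat_fraction(tg, data.frame(chrom = "c", start = 0L,
                                                  end = 40L)), 1.0)
  expect_equal(tag_repeat_fraction(tg, data.frame(chrom = "c", start = 50L,
                                                  end = 60L)), 0.0)
  expect_equal(tag_repeat_fraction(tg, data.frame(chrom = "c", start = 20L,
                                                  end = 40L)), 13 / 33)
  expect_equal(tag_repeat_fraction(tg, NULL), 0.0)
})

test_that("digest metrics implement the declared panel formulas", {
  m <- digest_metrics(4267589, 1367611, 173686597)
  expect_equal(m$pct_selected_portion, 100 * 1367611 / 4267589)
  expect_equal(m$predicted_snps, 2 * 33 * 1367611 / 5000)
  expect_equal(m$coverage_per_run, 1.9242e9 / 173686597)
  ## zero selection degrades gracefully
  expect_warning(m0 <- digest_metrics(10, 0, 0), "size window")
  expect_equal(m0$complexity_reduction_pct, 0)
  expect_equal(m0$predicted_snps, 0)
})

test_that("digest report counts repetitive fragments by terminal-tag overlap", {
  cviri <- enzyme_spec("CviRI", "TGCA", 2)
  set.seed(21)
  g <- c(chr = rand_dna(60000))
  fr <- digest(g, cviri, sequences = FALSE)
  rep_none <- compute_digest_report(fr, 60000, repeat_intervals = NULL)
  expect_identical(rep_none$n_repetitive_selected, 0L)
  expect_equal(rep_none$pct_repetitive_selected, 0)
  ## annotate the first selected fragment's 5' tag fully repetitive
  sel <- size_select(fr, 70, 200)
  bed <- data.frame(chrom = "chr", start = sel$start[1],
                    end = sel$start[1] + 33L)
  rp <- compute_digest_report(fr, 60000, repeat_intervals = bed)
  expect_identical(rp$n_repetitive_selected, 1L)
  expect_equal(rp$pct_selected_portion, 100 * nrow(sel) / nrow(fr))
  expect_true(rp$complexity_reduction_pct >= 0 &&
                rp$complexity_reduction_pct <= 100)
})
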