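## helper: a minimal mapped-alignment table for pileup construction
mk_aln <- function(seqs, pos, strand = "+", read_count = 1L,
                   mq = 40L, quality = NULL) {
  n <- length(seqs)
  if (is.null(quality)) quality <- strrep("?", nchar(seqs[1]))
  data.table::data.table(
    sequence = seqs, mapped = TRUE, chrom = "chr1", pos = as.integer(pos),
    strand = rep(strand, length.out = n),
    n_mismatches = 0L, n_best_hits = 1L,
    mapping_quality = rep(as.integer(mq), length.out = n),
    read_count = rep(as.integer(read_count), length.out = n),
    quality = rep(quality, length.out = n))
}

mk_cand <- function(pos, depth = 40L, alt_count = 20L, cq = 40L, mq = 40L,
                    ref = "A", alt = "C", chrom = "chr1") {
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    depth = as.integer(depth), alt_count = as.integer(alt_count),
    consensus_quality = as.integer(cq), max_mq = as.integer(mq),
    mq0_depth = 0L, tier = "candidate")[order(chrom, pos)]
}

test_that("pileup columns carry depth, alleles and qualities faithfully", {
  set.seed(2)
  ref <- c(chr1 = rand_dna(200))
  tag <- substr(ref[[1]], 51, 83)
  p1 <- build_pileup(mk_aln(tag, 50L), ref)
  expect_identical(nrow(p1), 33L)
  expect_true(all(p1$depth == 1L))
  expect_identical(p1$ref, strsplit(tag, "")[[1]])

  p2 <- build_pileup(mk_aln(tag, 50L, read_count = 2L), ref)
  expect_true(all(p2$depth == 2L))

  ## a minus-strand read contributes reference-oriented bases
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  p3 <- build_pileup(mk_aln(rc, 50L, strand = "-"), ref)
  expect_identical(p3[, paste0("n_", p3$ref[1]), with = FALSE][[1]][1], 1L)
  expect_identical(sum(p3$depth), 33L)

  expect_error(build_pileup(mk_aln(tag, 190L), ref), "past chromosome end")
})

test_that("pileup depth conservation holds on a full study", {
  res <- small_clean_run()
  mapped <- res$alignments[res$alignments$mapped == TRUE, ]
  expect_identical(sum(res$pileup$depth), 33L * sum(mapped$read_count))
})

test_that("candidate calling requires alt support above the error model", {
  set.seed(8)
  ref <- c(chr1 = rand_dna(200))
  tag <- substr(ref[[1]], 51, 83)
  ## ten reference-identical reads: no candidate
  p <- build_pileup(mk_aln(tag, 50L, read_count = 10L), ref)
  expect_identical(nrow(call_candidates(p)), 0L)

  ## 5 ref + 5 alt at one position (pooled heterozygous pattern)
  v <- strsplit(tag, "")[[1]]
  v[17] <- setdiff(c("A", "C", "G", "T"), v[17])[1]
  alt_tag <- paste(v, collapse = "")
  p2 <- build_pileup(rbind(mk_aln(tag, 50L, read_count = 5L),
                           mk_aln(alt_tag, 50L, read_count = 5L)), ref)
  cand <- call_candidates(p2)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$pos, 50L + 16L)
  expect_identical(cand$alt_count, 5L)
  expect_identical(cand$depth, 10L)
  expect_identical(cand$alt, v[17])

  ## a single low-quality (Q10) mismatching read is explained by error
  q <- strsplit(strrep("?", 33), "")[[1]]; q[17] <- "+"
  p3 <- build_pileup(rbind(
    mk_aln(tag, 50L, read_count = 30L),
    mk_aln(alt_tag, 50L, quality = paste(q, collapse = ""))), ref)
  expect_identical(nrow(call_candidates(p3)), 0L)
})

test_that("error-free spiked study recovers truth among candidates", {
  res <- small_clean_run()
  truth <- res$sim$truth
  snps <- truth[truth$type == "SNP", ]
  covered_alt <- res$sim_tags[res$sim_tags$parent == "alt" &
                                res$sim_tags$count >= 1L, ]
  fp <- res$footprints[res$footprints$unique == TRUE, ]
  disc <- logical(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    disc[i] <- any(covered_alt$chrom == snps$chrom[i] &
                     covered_alt$start <= snps$alt_pos[i] &
                     covered_alt$end > snps$alt_pos[i]) &&
      any(fp$chrom == snps$chrom[i] & fp$start <= snps$pos[i] &
            fp$end > snps$pos[i])
  }
  ## every covered spiked SNP in an unambiguous footprint must appear in
  ## the candidate list (errors are off in this study)
  key_c <- paste(res$candidates$chrom, res$candidates$pos,
                 res$candidates$alt)
  key_t <- paste(snps$chrom, snps$pos, snps$alt)
  found <- key_t %in% key_c
  expect_gt(sum(disc), 0L)
  expect_true(all(found[disc]))
})

test_that("the 10-bp window rule matches brute-force enumeration", {
  ## worked boundary cases
  expect_identical(window_rule_keep(rep("c", 3), c(100L, 105L, 109L)),
                   rep(FALSE, 3))
  expect_identical(window_rule_keep(rep("c", 3), c(100L, 105L, 110L)),
                   rep(TRUE, 3))
  expect_identical(window_rule_keep(rep("c", 2), c(100L, 109L)),
                   rep(TRUE, 2))
  ## property: random candidate sets against every-window enumeration
  set.seed(29)
  for (rep_i in 1:50) {
    n <- sample(1:60, 1)
    pos <- sort(sample(0:400, n))
    keep <- window_rule_keep(rep("c", n), pos)
    expect_identical(keep, oracle_window_keep(pos), info = rep_i)
  }
})

test_that("lenient rules: depth three, repeat exclusion, window purge", {
  cand <- mk_cand(c(100L, 300L, 500L), depth = c(2L, 3L, 40L))
  out <- filter_lenient(cand)
  expect_identical(out$pos, c(300L, 500L))   # depth 2 removed, 3 kept
  expect_true(all(out$tier == "lenient"))

  rep_bed <- data.frame(chrom = "chr1", start = 490L, end = 510L)
  out2 <- filter_lenient(cand, rep_bed)
  expect_identical(out2$pos, 300L)           # repeat position removed

  dense <- mk_cand(c(100L, 105L, 109L, 400L))
  out3 <- filter_lenient(dense)
  expect_identical(out3$pos, 400L)           # dense window purged entirely
  aud <- attr(out3, "audit")
  expect_identical(aud$pass_window, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("stringent rules: indel flank, depth ten, MQ forty, consensus ten", {
  base <- mk_cand(c(50L, 150L, 250L, 350L, 450L),
                  depth = c(9L, 10L, 40L, 40L, 40L),
                  cq = c(40L, 40L, 9L, 10L, 40L),
                  mq = c(40L, 40L, 40L, 40L, 25L))
  base$tier <- "lenient"
  out <- filter_stringent(base)
  ## depth 9 fails, depth 10 passes; CQ 9 fails, CQ 10 passes; MQ 25 fails
  expect_identical(out$pos, c(150L, 350L))
  expect_true(all(out$tier == "stringent"))

  ## indel proximity: distance 2 discarded, distance 4 survives
  cand <- mk_cand(c(100L, 200L))
  cand$tier <- "lenient"
  indels <- data.frame(chrom = "chr1", pos = c(102L, 204L),
                       length = c(1L, 1L))
  out2 <- filter_stringent(cand, indels)
  expect_identical(out2$pos, 200L)
  aud <- attr(out2, "audit")
  expect_identical(aud$pass_indel, c(FALSE, TRUE))
})

test_that("tiers nest and depth thresholds are monotone", {
  res <- small_clean_run()
  keyof <- function(x) paste(x$chrom, x$pos)
  expect_true(all(keyof(res$stringent) %in% keyof(res$lenient)))
  expect_true(all(keyof(res$lenient) %in% keyof(res$candidates)))
  ## raising the depth threshold shrinks the (pre-window) surviving set
  cand <- res$candidates
  for (d in c(3L, 10L, 20L)) {
    lo <- filter_lenient(cand, min_depth = d, max_per_window = 10000L)
    hi <- filter_lenient(cand, min_depth = d + 5L, max_per_window = 10000L)
    expect_true(all(keyof(hi) %in% keyof(lo)))
  }
})

test_that("cross-assembly exclusion: identity, duplication, deletion", {
  set.seed(47)
  ref <- c(chr1 = rand_dna(4000))
  idx <- build_index(ref)
  tag <- substr(ref[[1]], 1001, 1033)
  v <- strsplit(tag, "")[[1]]
  v[17] <- setdiff(c("A", "C", "G", "T"), v[17])[1]
  alt_tag <- paste(v, collapse = "")
  aln <- rbind(mk_aln(tag, 1000L, read_count = 10L),
               mk_aln(alt_tag, 1000L, read_count = 10L))
  pile <- build_pileup(aln, ref)
  cand <- call_candidates(pile)
  expect_identical(nrow(cand), 1L)

  ## identical second reference, unique region: retained
  keep <- cross_assembly_filter(cand, aln, ref)
  expect_identical(nrow(keep), 1L)

  ## second assembly duplicates the locus: excluded as multi-position
  ref_dup <- c(chr1 = paste0(ref[[1]], substr(ref[[1]], 901, 1200)))
  drop1 <- cross_assembly_filter(cand, aln, ref_dup)
  expect_identical(nrow(drop1), 0L)
  expect_true(attr(drop1, "audit")$multi_position)

  ## region deleted from the second assembly: unalignable, excluded
  ref_del <- c(chr1 = paste0(substr(ref[[1]], 1, 800),
                             substr(ref[[1]], 1301, 4000)))
  drop2 <- cross_assembly_filter(cand, aln, ref_del)
  expect_identical(nrow(drop2), 0L)

  ## repeat-masking the locus on the second assembly also excludes it
  drop3 <- cross_assembly_filter(cand, aln, ref,
                                 second_repeats = data.frame(
                                   chrom = "chr1", start = 950L, end = 1100L))
  expect_identical(nrow(drop3), 0L)
  expect_true(attr(drop3, "audit")$unalignable_masked)
})

test_that("flank extraction brackets the alleles and truncates at ends", {
  set.seed(53)
  ref <- c(chr1 = rand_dna(3000))
  cand <- mk_cand(c(1000L, 10L),
                  ref = substr(ref[[1]], c(1001, 11), c(1001, 11)))[order(pos)]
  fl <- extract_flanks(cand, ref, flank = 60L)
  full <- fl[fl$pos == 1001L, ]
  expect_identical(nchar(full$context), 60L + 60L + 5L)  # flanks + "[X/Y]"
  expect_false(full$truncated)
  ## stripping the bracket reproduces the reference substring
  stripped <- sub("\\[(.)/.\\]", "\\1", full$context)
  expect_identical(stripped, substr(ref[[1]], 1001 - 60, 1001 + 60))
  short <- fl[fl$pos == 11L, ]
  expect_true(short$truncated)
  expect_identical(nchar(short$context), 10L + 60L + 5L)
})

test_that("VCF output round-trips through an independent reader", {
  skip_if_not_installed("VariantAnnotation")
  set.seed(59)
  ref <- c(chr1 = rand_dna(1000), chr2 = rand_dna(800))
  cand <- rbind(mk_cand(99L, depth = 12L, alt_count = 6L, cq = 33L),
                mk_cand(500L, depth = 25L, alt_count = 11L, cq = 40L,
                        chrom = "chr2", ref = "G", alt = "T"))
  cand$ref <- c(substr(ref[[1]], 100, 100), substr(ref[[2]], 501, 501))
  cand$alt <- vapply(cand$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  cand$tier <- c("lenient", "stringent")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cand, ref, path)

  vcf <- VariantAnnotation::readVcf(path)
  expect_identical(unname(BiocGenerics::start(
    SummarizedExperiment::rowRanges(vcf))), c(100L, 501L))
  expect_identical(as.character(VariantAnnotation::ref(vcf)), cand$ref)
  expect_identical(as.character(unlist(VariantAnnotation::alt(vcf))),
                   cand$alt)
  info <- VariantAnnotation::info(vcf)
  expect_identical(info$DP, cand$depth)
  expect_identical(info$AC, cand$alt_count)
  expect_identical(info$TIER, cand$tier)
  filt <- VariantAnnotation::filt(vcf)
  expect_identical(filt, c("lenient", "PASS"))

  ## empty set gives a parseable header-only file
  write_vcf(cand[0, ], ref, path)
  expect_identical(nrow(VariantAnnotation::readVcf(path)), 0L)

  ## unsorted input is rejected
  expect_error(write_vcf(cand[2:1, ], ref, path), "sorted")
})
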