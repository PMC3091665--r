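## Pileup construction, candidate SNP calling with a consensus-quality score,
## the lenient and stringent filter ladders, cross-assembly exclusion,
## flanking-context extraction and VCF output.
##
## Filter semantics follow the two published stringency ladders:
##  lenient   — read depth >= 3; not in a repeat region; no 10-bp window with
##              3 or more candidate SNPs (all candidates in a violating
##              window are removed); reads with 'N' discarded upstream.
##  stringent — applied on top of lenient: farther than 3 bp from any indel;
##              read depth >= 10; covered by at least one read of mapping
##              quality >= 40; consensus quality >= 10; window rule re-checked.

#' Build a pileup from tag alignments
#'
#' Every reference base covered by a mapped tag receives one column carrying
#' per-allele read counts and summed base qualities, the maximum mapping
#' quality among covering reads, and the depth contributed by ambiguous
#' (MQ 0) placements. Multi-hit alignments contribute to depth — that is
#' what makes repeat pile-up visible — but are separable via `mq0_depth`.
#'
#' @param alignments Mapped tag table: [align_tags()] output merged with
#'   `read_count` and `quality` columns (see [collapse_unique()]).
#' @param reference The reference genome ([Biostrings::DNAStringSet]).
#' @return A `data.table` keyed by (`chrom`, `pos`): per-allele counts
#'   `n_A..n_T`, quality sums `q_A..q_T`, `depth`, `max_mq`, `mq0_depth`,
#'   `ref`.
#' @export
build_pileup <- function(alignments, reference) {
  reference <- as_genome(reference)
  aln <- as.data.table(alignments)[mapped == TRUE]
  if (nrow(aln) == 0L) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      n_A = integer(), n_C = integer(), n_G = integer(),
                      n_T = integer(), q_A = numeric(), q_C = numeric(),
                      q_G = numeric(), q_T = numeric(), depth = integer(),
                      max_mq = integer(), mq0_depth = integer()))
  }
  if (!"read_count" %in% names(aln)) aln[, read_count := 1L]
  len <- nchar(aln$sequence[1L])
  lens <- stats::setNames(BiocGenerics::width(reference), names(reference))
  if (any(aln$pos + len > lens[aln$chrom])) {
    stop("alignment extends past chromosome end")
  }
  ## reference-oriented read sequence and quality
  minus <- aln$strand == "-"
  oriented <- aln$sequence
  oriented[minus] <- revcomp_chr(oriented[minus])
  oq <- aln$quality
  if (is.null(oq)) oq <- strrep("?", len)
  rev_str <- function(x) vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
  oq[minus] <- rev_str(oq[minus])

  n <- nrow(aln)
  idx <- rep(seq_len(n), each = len)
  long <- data.table(
    chrom = aln$chrom[idx],
    pos = aln$pos[idx] + rep(seq_len(len) - 1L, times = n),
    base = unlist(strsplit(oriented, ""), use.names = FALSE),
    w = aln$read_count[idx],
    q = (unlist(lapply(oq, utf8ToInt), use.names = FALSE) - 33L) *
      aln$read_count[idx],
    mq = aln$mapping_quality[idx]
  )
  counts <- long[, list(n = sum(w), qs = sum(q)), by = list(chrom, pos, base)]
  wide <- data.table::dcast(counts, chrom + pos ~ base,
                            value.var = c("n", "qs"), fill = 0)
  for (b in BASES) {
    if (!paste0("n_", b) %in% names(wide)) wide[, paste0("n_", b) := 0L]
    if (!paste0("qs_", b) %in% names(wide)) wide[, paste0("qs_", b) := 0]
  }
  setnames(wide, paste0("qs_", BASES), paste0("q_", BASES), skip_absent = TRUE)
  colstats <- long[, list(max_mq = max(mq), mq0_depth = sum(w[mq == 0L])),
                   by = list(chrom, pos)]
  pile <- merge(wide, colstats, by = c("chrom", "pos"))
  pile[, depth := n_A + n_C + n_G + n_T]
  ## reference base per column
  pile[, ref := {
    s <- reference[[chrom[1L]]]
    as.character(Biostrings::Views(s, start = pos + 1L, width = 1L))
  }, by = chrom]
  setorder(pile, chrom, pos)
  data.table::setcolorder(
    pile, c("chrom", "pos", "ref", paste0("n_", BASES), paste0("q_", BASES),
            "depth", "max_mq", "mq0_depth"))
  pile[]
}

## Phred-scaled confidence that the alt evidence is not base-calling error:
## p = P(Binomial(depth, e) >= alt_count), e = 10^(-mean alt base quality/10).
consensus_quality <- function(alt_count, depth, alt_qual_sum) {
  qbar <- alt_qual_sum / pmax(alt_count, 1L)
  e <- pmin(10^(-qbar / 10), 0.75)
  p <- pbinom(alt_count - 1L, depth, e, lower.tail = FALSE)
  q <- ifelse(p <= 0, 40, -10 * log10(p))
  as.integer(pmin(40, pmax(0, round(q))))
}

#' Call candidate SNPs from a pileup
#'
#' A column yields a candidate when its best-supported non-reference allele
#' has at least `min_alt_reads` supporting reads and the consensus quality of
#' that evidence is at least `min_consensus` (default 1, i.e. the alt
#' evidence must exceed what the base qualities alone would explain; without
#' this gate every singleton sequencing error at a covered column would enter
#' the candidate list and poison the 10-bp window rule). Only the single
#' best-supported alt allele is considered (a pooled two-inbred design
#' implies biallelic sites). Columns whose reference base is 'N' are skipped.
#'
#' @param pileup Output of [build_pileup()].
#' @param min_alt_reads Minimum alt-supporting reads (default 1).
#' @param min_consensus Minimum consensus quality to enter the candidate
#'   list (default 1).
#' @return `data.table` of candidates: `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `depth`, `alt_count`, `consensus_quality`, `max_mq`,
#'   `mq0_depth`, `tier` (`"candidate"`).
#' @export
call_candidates <- function(pileup, min_alt_reads = 1L, min_consensus = 1L) {
  p <- as.data.table(pileup)[ref %in% BASES]
  if (nrow(p) == 0L) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), consensus_quality = integer(),
                      max_mq = integer(), mq0_depth = integer(),
                      tier = character()))
  }
  cnt <- as.matrix(p[, paste0("n_", BASES), with = FALSE])
  qs <- as.matrix(p[, paste0("q_", BASES), with = FALSE])
  ri <- match(p$ref, BASES)
  cnt[cbind(seq_len(nrow(cnt)), ri)] <- -1L   # exclude ref allele from argmax
  ai <- max.col(cnt, ties.method = "first")
  ac <- cnt[cbind(seq_len(nrow(cnt)), ai)]
  keep <- ac >= max(min_alt_reads, 1L)
  out <- p[keep, list(chrom, pos, ref, depth, max_mq, mq0_depth)]
  ai <- ai[keep]
  out[, alt := BASES[ai]]
  out[, alt_count := ac[keep]]
  aq <- qs[keep, , drop = FALSE][cbind(seq_len(nrow(out)), ai)]
  out[, consensus_quality := consensus_quality(alt_count, depth, aq)]
  out <- out[consensus_quality >= min_consensus]
  out[, tier := "candidate"]
  setorder(out, chrom, pos)
  data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "depth",
                                 "alt_count", "consensus_quality", "max_mq",
                                 "mq0_depth", "tier"))
  out[]
}

#' Remove candidates violating the 10-bp window rule
#'
#' A window is every reference interval `[p, p + window)`. If any window
#' contains `>= max_per_window + 1` candidates, all candidates in that
#' window are removed. Positions `p` and `p + window - 1` co-occupy a
#' window; `p` and `p + window` do not.
#'
#' @param chrom,pos Candidate coordinates (0-based).
#' @param window Window width in bp (default 10).
#' @param max_per_window Maximum candidates tolerated per window (default 2).
#' @return Logical keep vector along the input.
#' @export
window_rule_keep <- function(chrom, pos, window = 10L, max_per_window = 2L) {
  n <- length(pos)
  keep <- rep(TRUE, n)
  if (n == 0L) return(keep)
  ord <- order(chrom, pos)
  for (ch in unique(chrom)) {
    i <- ord[chrom[ord] == ch]
    p <- pos[i]
    ## hi[j]: index of last candidate within [p_j, p_j + window - 1]
    hi <- findInterval(p + window - 1L, p)
    viol <- which(hi - seq_along(p) + 1L > max_per_window)
    if (length(viol)) {
      rm <- logical(length(p))
      for (j in viol) rm[j:hi[j]] <- TRUE
      keep[i[rm]] <- FALSE
    }
  }
  keep
}

#' Lenient-tier SNP filtering
#'
#' Keeps candidates with read depth of at least `min_depth` (default 3) that
#' do not lie inside a repeat interval (point-in-interval test), then removes
#' every candidate falling in a 10-bp window holding three or more of the
#' surviving candidates.
#'
#' @param candidates Output of [call_candidates()].
#' @param repeat_intervals Repeat annotation (`chrom`/`start`/`end`,
#'   0-based half-open) or `NULL`.
#' @param min_depth Minimum supporting read depth (default 3).
#' @param window,max_per_window Window-rule parameters (default 10 bp, 2).
#' @return The surviving candidates with `tier = "lenient"`. The full
#'   per-rule audit is attached as `attr(, "audit")`.
#' @export
filter_lenient <- function(candidates, repeat_intervals = NULL,
                           min_depth = 3L, window = 10L,
                           max_per_window = 2L) {
  cand <- as.data.table(candidates)
  audit <- cand[, list(chrom, pos, ref, alt)]
  audit[, pass_min_reads := cand$depth >= min_depth]
  audit[, pass_not_repeat := !positions_in_intervals(cand$chrom, cand$pos,
                                                     repeat_intervals)]
  pre <- audit$pass_min_reads & audit$pass_not_repeat
  audit[, pass_window := TRUE]
  idx <- which(pre)
  if (length(idx)) {
    audit$pass_window[idx] <- window_rule_keep(
      cand$chrom[idx], cand$pos[idx], window, max_per_window)
  }
  keep <- pre & audit$pass_window
  out <- cand[keep]
  if (nrow(out)) out[, tier := "lenient"]
  data.table::setattr(out, "audit", audit[])
  out[]
}

#' Stringent-tier SNP filtering
#'
#' Applied on top of the lenient tier. Keeps candidates that are farther
#' than `indel_flank` bp from any indel, have read depth of at least
#' `min_depth` (default 10), are covered by at least one read with mapping
#' quality `min_mq` or better, and have consensus quality of at least
#' `min_consensus`; the 10-bp window rule is then re-applied to the
#' survivors.
#'
#' @param candidates Lenient-tier candidates from [filter_lenient()].
#' @param indels Indel track: `chrom`, `pos` (0-based), `length` (bp on the
#'   reference; 0 for insertions), or `NULL` for none.
#' @param min_depth Minimum read depth (default 10).
#' @param indel_flank Exclusion distance around indels in bp; a SNP at
#'   distance `<= indel_flank` is discarded (default 3, inclusive boundary).
#' @param min_mq Required mapping quality of the best covering read
#'   (default 40, read as "at least 40": 40 is also the scale maximum, so a
#'   strict reading would discard everything).
#' @param min_consensus Minimum consensus quality (default 10).
#' @param window,max_per_window Window-rule parameters.
#' @return Surviving candidates with `tier = "stringent"`; per-rule audit in
#'   `attr(, "audit")`.
#' @export
filter_stringent <- function(candidates, indels = NULL, min_depth = 10L,
                             indel_flank = 3L, min_mq = 40L,
                             min_consensus = 10L, window = 10L,
                             max_per_window = 2L) {
  cand <- as.data.table(candidates)
  audit <- cand[, list(chrom, pos, ref, alt)]
  if (!is.null(indels) && nrow(indels) > 0L) {
    reg <- data.table(chrom = indels$chrom,
                      start = indels$pos - indel_flank,
                      end = indels$pos + pmax(indels$length, 1L) + indel_flank)
    reg[, start := pmax(start, 0L)]
    audit[, pass_indel := !positions_in_intervals(cand$chrom, cand$pos, reg)]
  } else {
    audit[, pass_indel := TRUE]
  }
  audit[, pass_min_reads := cand$depth >= min_depth]
  audit[, pass_mq := cand$max_mq >= min_mq]
  audit[, pass_consensus := cand$consensus_quality >= min_consensus]
  pre <- audit$pass_indel & audit$pass_min_reads & audit$pass_mq &
    audit$pass_consensus
  audit[, pass_window := TRUE]
  idx <- which(pre)
  if (length(idx)) {
    audit$pass_window[idx] <- window_rule_keep(
      cand$chrom[idx], cand$pos[idx], window, max_per_window)
  }
  keep <- pre & audit$pass_window
  out <- cand[keep]
  if (nrow(out)) out[, tier := "stringent"]
  data.table::setattr(out, "audit", audit[])
  out[]
}

#' Cross-assembly / multi-position exclusion
#'
#' Re-aligns the short-read sequence supporting each candidate onto a second
#' (e.g. newer) assembly and excludes candidates whose tag has more than one
#' best position in that assembly, and candidates whose tag cannot be placed
#' on the repeat-masked second assembly at all.
#'
#' @param candidates Candidate table (any tier).
#' @param alignments Mapped tag table used for calling (with `read_count`).
#' @param second_reference The second assembly (may equal the first).
#' @param second_repeats Repeat annotation of the second assembly, or `NULL`
#'   (no masking).
#' @param max_mm Mismatch tolerance for re-alignment (default 2).
#' @return Retained candidates; exclusion reasons in `attr(, "audit")`
#'   (`multi_position`, `unalignable_masked`).
#' @export
cross_assembly_filter <- function(candidates, alignments, second_reference,
                                  second_repeats = NULL, max_mm = 2L) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L) {
    data.table::setattr(cand, "audit", cand)
    return(cand)
  }
  aln <- as.data.table(alignments)[mapped == TRUE]
  len <- nchar(aln$sequence[1L])
  tagseq <- supporting_tag_sequences(cand, aln, len)
  second_reference <- as_genome(second_reference)
  idx2 <- build_index(second_reference)
  masked <- mask_genome(second_reference, second_repeats)
  idx2m <- build_index(masked)
  multi <- logical(nrow(cand))
  nohit <- logical(nrow(cand))
  done <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    s <- tagseq[i]
    if (is.na(s)) { nohit[i] <- TRUE; next }
    res <- get0(s, envir = done)
    if (is.null(res)) {
      pl <- find_placements(s, idx2, max_mm)
      res <- c(
        multi = nrow(pl) > 0L && sum(pl$mism == min(pl$mism)) > 1L,
        none_masked = nrow(find_placements(s, idx2m, max_mm)) == 0L
      )
      assign(s, res, envir = done)
    }
    multi[i] <- res[["multi"]]
    nohit[i] <- res[["none_masked"]]
  }
  audit <- cand[, list(chrom, pos, ref, alt)]
  audit[, multi_position := multi]
  audit[, unalignable_masked := nohit]
  out <- cand[!(multi | nohit)]
  data.table::setattr(out, "audit", audit[])
  out[]
}

## For each candidate, the read-orientation sequence of the highest-coverage
## mapped tag that covers the site and carries the alt allele.
supporting_tag_sequences <- function(cand, aln, len) {
  out <- rep(NA_character_, nrow(cand))
  setorder(aln, chrom, pos)
  if (!"read_count" %in% names(aln)) aln[, read_count := 1L]
  for (ch in unique(cand$chrom)) {
    a <- aln[chrom == ch]
    if (nrow(a) == 0L) next
    oriented <- a$sequence
    minus <- a$strand == "-"
    oriented[minus] <- revcomp_chr(oriented[minus])
    ci <- which(cand$chrom == ch)
    lo <- findInterval(cand$pos[ci] - len, a$pos) + 1L
    hi <- findInterval(cand$pos[ci], a$pos)
    for (j in seq_along(ci)) {
      if (hi[j] < lo[j]) next
      rows <- lo[j]:hi[j]
      off <- cand$pos[ci[j]] - a$pos[rows] + 1L
      okrow <- off >= 1L & off <= len
      rows <- rows[okrow]; off <- off[okrow]
      carries <- substr(oriented[rows], off, off) == cand$alt[ci[j]]
      rows <- rows[carries]
      if (length(rows)) {
        out[ci[j]] <- a$sequence[rows[which.max(a$read_count[rows])]]
      }
    }
  }
  out
}

## Replace repeat intervals with N (hard masking).
mask_genome <- function(genome, repeats) {
  genome <- as_genome(genome)
  if (is.null(repeats) || nrow(repeats) == 0L) return(genome)
  out <- lapply(names(genome), function(ch) {
    s <- as.character(genome[[ch]])
    r <- repeats[repeats$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      substr(s, r$start[i] + 1L, r$end[i]) <-
        strrep("N", r$end[i] - r$start[i])
    }
    s
  })
  Biostrings::DNAStringSet(stats::setNames(unlist(out), names(genome)))
}

#' Extract flanking context around candidate SNPs
#'
#' Returns `flank` bases of reference sequence either side of each SNP with
#' the site written as `[ref/alt]`, the format used for assay design.
#' Flanks are truncated at chromosome ends and flagged.
#'
#' @param candidates Candidate table.
#' @param reference Reference genome.
#' @param flank Flank length in bp (default 60).
#' @return `data.table`: `id`, `chrom`, `pos` (1-based), `context`,
#'   `truncated`.
#' @export
extract_flanks <- function(candidates, reference, flank = 60L) {
  reference <- as_genome(reference)
  cand <- as.data.table(candidates)
  n <- nrow(cand)
  context <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    s <- reference[[cand$chrom[i]]]
    p <- cand$pos[i]                 # 0-based
    left <- max(0L, p - flank)
    right <- min(length(s), p + 1L + flank)
    trunc[i] <- (p - flank < 0L) || (p + 1L + flank > length(s))
    lf <- if (p > left) as.character(Biostrings::subseq(s, left + 1L, p)) else ""
    rf <- if (right > p + 1L)
      as.character(Biostrings::subseq(s, p + 2L, right)) else ""
    context[i] <- paste0(lf, "[", cand$ref[i], "/", cand$alt[i], "]", rf)
  }
  data.table(
    id = sprintf("%s_%d", cand$chrom, cand$pos + 1L),
    chrom = cand$chrom, pos = cand$pos + 1L,
    context = context, truncated = trunc
  )
}

#' Write candidates to VCF
#'
#' VCF 4.2 with 1-based positions. INFO carries depth (`DP`), alt read count
#' (`AC`), consensus quality (`CQ`), best covering mapping quality (`MQ`) and
#' tier (`TIER`); FILTER encodes the tier (`PASS` for stringent-tier calls,
#' `lenient`, `raw`).
#'
#' @param candidates Candidate table, sorted by chromosome and position.
#' @param reference Reference genome (for contig header lines).
#' @param path Output path.
#' @param extra_header Optional character vector of additional `##` lines
#'   (e.g. provenance stamps).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(candidates, reference, path, extra_header = NULL) {
  reference <- as_genome(reference)
  cand <- as.data.table(candidates)
  if (nrow(cand) > 1L) {
    o <- order(cand$chrom, cand$pos)
    if (!identical(o, seq_len(nrow(cand)))) {
      stop("candidates must be sorted by chromosome and position")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrsnp",
    extra_header,
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            BiocGenerics::width(reference)),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at site">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alt-supporting read count">',
    '##INFO=<ID=CQ,Number=1,Type=Integer,Description="Consensus quality">',
    '##INFO=<ID=MQ,Number=1,Type=Integer,Description="Best covering mapping quality">',
    '##INFO=<ID=TIER,Number=1,Type=String,Description="Filter tier reached">',
    '##FILTER=<ID=lenient,Description="Passed lenient tier only">',
    '##FILTER=<ID=raw,Description="Candidate below lenient tier">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(cand) > 0L) {
    filt <- c(candidate = "raw", lenient = "lenient", stringent = "PASS")
    lines <- c(hdr, sprintf(
      "%s\t%d\t%s\t%s\t%s\t%d\t%s\tDP=%d;AC=%d;CQ=%d;MQ=%d;TIER=%s",
      cand$chrom, cand$pos + 1L,
      sprintf("%s_%d", cand$chrom, cand$pos + 1L),
      cand$ref, cand$alt, cand$consensus_quality,
      unname(filt[cand$tier]), cand$depth, cand$alt_count,
      cand$consensus_quality, cand$max_mq, cand$tier))
  }
  writeLines(lines, path)
  invisible(path)
}
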