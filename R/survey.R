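## Descriptive survey analyses: coverage histograms and read-count classes,
## sliding-window repetitiveness/GC vs coverage, SNP-position-in-read
## distribution, clone-library QC classification, validation-rate accounting.

#' Histogram of per-tag read coverage
#'
#' Bins unique-tag read counts (bin width 1) over tags with at least
#' `min_count` reads; probabilities sum to 1.
#'
#' @param read_counts Integer vector of per-unique-tag read counts.
#' @param min_count Lowest coverage retained (default 3).
#' @return `data.table` with `coverage`, `n`, `prob` (empty when no tag
#'   reaches `min_count`).
#' @export
coverage_histogram <- function(read_counts, min_count = 3L) {
  x <- read_counts[read_counts >= min_count]
  if (length(x) == 0L) {
    return(data.table(coverage = integer(), n = integer(), prob = numeric()))
  }
  tab <- table(x)
  data.table(coverage = as.integer(names(tab)),
             n = as.integer(tab),
             prob = as.integer(tab) / length(x))
}

#' Per-window repetitiveness, GC content and read coverage
#'
#' Tiles each chromosome with non-overlapping windows (step = width by
#' default; the analysis the window comparison emulates used 10-kbp windows)
#' and reports per window the repeat-base fraction, the GC fraction ('N'
#' excluded from the denominator) and the mapped read count, reads assigned
#' to the window containing their leftmost mapped coordinate and weighted by
#' their duplicate read count.
#'
#' @param reference Reference genome.
#' @param repeats Repeat annotation table or `NULL`.
#' @param alignments Mapped tag table with `read_count`.
#' @param window Window width in bp (default 10,000).
#' @param step Window step in bp (default `window`, i.e. tiling).
#' @return `data.table`: `chrom`, `start`, `end` (0-based half-open),
#'   `repetitive_fraction`, `gc_fraction`, `read_count`.
#' @export
window_stats <- function(reference, repeats, alignments, window = 10000L,
                         step = window) {
  reference <- as_genome(reference)
  aln <- as.data.table(alignments)[mapped == TRUE]
  if (!"read_count" %in% names(aln)) aln[, read_count := 1L]
  out <- lapply(names(reference), function(ch) {
    L <- length(reference[[ch]])
    starts <- seq(0L, max(L - 1L, 0L), by = step)
    ends <- pmin(starts + window, L)
    v <- Biostrings::Views(reference[[ch]], start = starts + 1L, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
    w <- data.table(chrom = ch, start = starts, end = ends)
    w[, repetitive_fraction :=
        interval_overlap_bp(w, repeats) / (end - start)]
    w[, gc_fraction := ifelse(acgt > 0, gc / acgt, NA_real_)]
    a <- aln[chrom == ch]
    rc <- numeric(length(starts))
    if (nrow(a) > 0L) {
      wi <- findInterval(a$pos, starts)
      agg <- tapply(a$read_count, wi, sum)
      rc[as.integer(names(agg))] <- as.numeric(agg)
    }
    w[, read_count := rc]
    w
  })
  rbindlist(out)
}

#' Pearson product-moment correlation
#'
#' Standard product-moment correlation
#' \eqn{r = \sum (x_i-\bar x)(y_i-\bar y) / (s_x s_y (n-1))}; returns `NA`
#' when either variable has zero variance.
#'
#' @param x,y Equal-length numeric vectors (length at least 3).
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Repeat enrichment of high-coverage tags
#'
#' Classifies each mapped unique tag as repetitive when its best-placement
#' footprint overlaps the repeat annotation by at least one base, and
#' reports the repetitive percentage among tags with more than `threshold`
#' reads and among tags with `threshold` reads or fewer.
#'
#' @param alignments Mapped tag table with `read_count`.
#' @param repeats Repeat annotation table or `NULL`.
#' @param threshold Read-count split point (default 200).
#' @param tag_len Tag footprint length (default 33).
#' @return List with `pct_repetitive_above`, `pct_repetitive_below`,
#'   `n_above`, `n_below`. Percentages are `NA` when a class is empty;
#'   both are 0 when no repeats are annotated.
#' @export
high_coverage_repeat_enrichment <- function(alignments, repeats,
                                            threshold = 200L,
                                            tag_len = 33L) {
  aln <- as.data.table(alignments)[mapped == TRUE]
  if (!"read_count" %in% names(aln)) aln[, read_count := 1L]
  fp <- data.table(chrom = aln$chrom, start = aln$pos,
                   end = aln$pos + tag_len)
  repe <- interval_overlap_bp(fp, repeats) > 0L
  above <- aln$read_count > threshold
  pct <- function(sel) {
    if (!any(sel)) return(NA_real_)
    100 * sum(repe[sel]) / sum(sel)
  }
  list(pct_repetitive_above = if (is.null(repeats) || nrow(repeats) == 0L) {
         if (any(above)) 0 else NA_real_
       } else pct(above),
       pct_repetitive_below = if (is.null(repeats) || nrow(repeats) == 0L) {
         if (any(!above)) 0 else NA_real_
       } else pct(!above),
       n_above = sum(above), n_below = sum(!above))
}

#' Distribution of SNPs over read positions
#'
#' For every (candidate, supporting read) pair — a mapped tag covering the
#' candidate whose reference-oriented base at the site equals the alt
#' allele, weighted by its duplicate read count — increments the 1-based
#' read position (in sequencing orientation) of the mismatch.
#'
#' @param candidates Candidate table.
#' @param alignments Mapped tag table with `read_count`.
#' @param tag_len Read length (default 33).
#' @return Integer vector of counts, named `1..tag_len`.
#' @export
snp_read_position_distribution <- function(candidates, alignments,
                                           tag_len = 33L) {
  counts <- stats::setNames(integer(tag_len), seq_len(tag_len))
  cand <- as.data.table(candidates)
  aln <- as.data.table(alignments)[mapped == TRUE]
  if (nrow(cand) == 0L || nrow(aln) == 0L) return(counts)
  if (!"read_count" %in% names(aln)) aln[, read_count := 1L]
  setorder(aln, chrom, pos)
  for (ch in unique(cand$chrom)) {
    a <- aln[chrom == ch]
    if (nrow(a) == 0L) next
    oriented <- a$sequence
    minus <- a$strand == "-"
    oriented[minus] <- revcomp_chr(oriented[minus])
    ci <- which(cand$chrom == ch)
    lo <- findInterval(cand$pos[ci] - tag_len, a$pos) + 1L
    hi <- findInterval(cand$pos[ci], a$pos)
    for (j in seq_along(ci)) {
      if (hi[j] < lo[j]) next
      rows <- lo[j]:hi[j]
      off <- cand$pos[ci[j]] - a$pos[rows] + 1L   # ref-orientation offset
      ok <- off >= 1L & off <= tag_len
      rows <- rows[ok]; off <- off[ok]
      carries <- substr(oriented[rows], off, off) == cand$alt[ci[j]]
      rows <- rows[carries]; off <- off[carries]
      if (!length(rows)) next
      ## read position in sequencing orientation
      rp <- ifelse(a$strand[rows] == "-", tag_len + 1L - off, off)
      add <- tapply(a$read_count[rows], rp, sum)
      counts[as.integer(names(add))] <-
        counts[as.integer(names(add))] + as.integer(add)
    }
  }
  counts
}

#' Validation-rate accounting
#'
#' @param n_positive Confirmed positives.
#' @param n_tested Total tested (> 0).
#' @param decimals Decimal places of the reported percentage (half-up
#'   rounding; default 0).
#' @return A one-row `data.frame`: `n_tested`, `n_positive`, `rate_pct`.
#' @examples
#' rate(52, 61)        # 85
#' rate(113, 171, 1)   # 66.1
#' @export
rate <- function(n_positive, n_tested, decimals = 0L) {
  if (n_tested <= 0) stop("n_tested must be positive")
  if (n_positive < 0 || n_positive > n_tested) {
    stop("n_positive must be in [0, n_tested]")
  }
  data.frame(n_tested = n_tested, n_positive = n_positive,
             rate_pct = round_half_up(100 * n_positive / n_tested, decimals))
}

## Half-up rounding to `d` decimals (R's round() is round-half-even).
round_half_up <- function(x, d = 0L) {
  floor(x * 10^d + 0.5) / 10^d
}

#' Classify clone-library sequences by genome hit count
#'
#' Library-QC accounting: good-quality clone sequences are classified as
#' locus-specific (exactly one genomic hit), multi-hit (more than one) or
#' no-hit, with percentages over the good-sequence total.
#'
#' @param n_single,n_multi,n_none Counts per class. Alternatively pass
#'   `hit_counts`, a per-clone vector of best-hit counts, and the three
#'   are derived.
#' @param n_good Total good-quality sequences; must equal the class sum.
#' @param hit_counts Optional per-clone hit-count vector.
#' @param decimals Decimal places (default 1).
#' @return `data.frame` with one row per class: `class`, `n`, `rate_pct`.
#' @examples
#' classify_clone_hits(74, 27, 53, n_good = 154)
#' @export
classify_clone_hits <- function(n_single = NULL, n_multi = NULL,
                                n_none = NULL, n_good = NULL,
                                hit_counts = NULL, decimals = 1L) {
  if (!is.null(hit_counts)) {
    n_single <- sum(hit_counts == 1L)
    n_multi <- sum(hit_counts > 1L)
    n_none <- sum(hit_counts == 0L)
    if (is.null(n_good)) n_good <- length(hit_counts)
  }
  if (n_single + n_multi + n_none != n_good) {
    stop("class counts (", n_single, " + ", n_multi, " + ", n_none,
         ") do not partition n_good (", n_good, ")")
  }
  data.frame(
    class = c("locus_specific", "multi_hit", "no_hit"),
    n = c(n_single, n_multi, n_none),
    rate_pct = round_half_up(100 * c(n_single, n_multi, n_none) / n_good,
                             decimals)
  )
}
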