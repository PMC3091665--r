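## Ungapped seed-and-verify alignment of fixed-length tags.
##
## Tags are split into max_mismatches + 1 non-overlapping seeds of the index
## k-mer length; by pigeonhole, any placement with <= max_mismatches leaves at
## least one seed exact, so exact-seed lookup followed by Hamming verification
## finds every qualifying placement. MAQ is not re-implemented; a declared
## mapping-quality proxy stands in for it (see align_tags).

## char -> integer code: A=1 C=2 G=3 T=4, anything else (incl. N) = 0.
.code_map <- local({
  m <- integer(256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m[utf8ToInt("a")] <- 1L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("g")] <- 3L; m[utf8ToInt("t")] <- 4L
  m
})

encode_dna <- function(x) .code_map[utf8ToInt(x)]

#' Collapse reads into unique tag sequences
#'
#' Groups reads by exact sequence identity (first-appearance order), counts
#' reads per unique sequence, and summarises the read-count classes. Unique
#' sequences containing an 'N' are counted in the summary but flagged for
#' exclusion from alignment input, matching the rule that short reads with an
#' 'N' are discarded.
#'
#' @param reads `data.table`/data.frame with columns `sequence` and
#'   (optionally) `quality`; e.g. from [read_fastq()] or
#'   [simulate_tag_reads()].
#' @return A list:
#'   \describe{
#'     \item{tags}{`data.table` of `sequence`, `read_count`, `has_N`,
#'       `quality` (quality string of the first read seen).}
#'     \item{summary}{list with `n_unique`, `pct_single_read`,
#'       `pct_multi_read`, `pct_with_N`, `n_reads`.}
#'   }
#' @export
collapse_unique <- function(reads) {
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) {
    return(list(
      tags = data.table(sequence = character(), read_count = integer(),
                        has_N = logical(), quality = character()),
      summary = list(n_unique = 0L, pct_single_read = 0, pct_multi_read = 0,
                     pct_with_N = 0, n_reads = 0L)))
  }
  if (length(unique(nchar(reads$sequence))) != 1L) {
    stop("reads must have uniform length")
  }
  if (!"quality" %in% names(reads)) reads$quality <- ""
  tags <- reads[, list(read_count = .N, quality = quality[1L]),
                by = sequence]
  tags[, has_N := grepl("N", sequence, fixed = TRUE)]
  n_u <- nrow(tags)
  list(
    tags = tags[],
    summary = list(
      n_unique = n_u,
      pct_single_read = 100 * sum(tags$read_count == 1L) / n_u,
      pct_multi_read = 100 * sum(tags$read_count > 1L) / n_u,
      pct_with_N = 100 * sum(tags$has_N) / n_u,
      n_reads = nrow(reads)
    )
  )
}

#' Build an exact-seed k-mer index of a reference
#'
#' Indexes every k-mer start position of the forward strand (reverse-strand
#' hits are found by querying the reverse complement of the tag). k-mers
#' containing 'N' are not indexed. Chromosomes are concatenated with N
#' spacers longer than any tag so no placement can span a boundary.
#'
#' @param reference Named [Biostrings::DNAStringSet] or character vector.
#' @param k Seed length (default 11; a 33-mer then carries 3 non-overlapping
#'   seeds, complete for up to 2 mismatches).
#' @return A `tag_index` object.
#' @export
build_index <- function(reference, k = 11L) {
  reference <- as_genome(reference)
  if (length(reference) == 0L) stop("reference is empty")
  k <- as.integer(k)
  spacer <- strrep("N", 40L)
  chroms <- names(reference)
  lens <- BiocGenerics::width(reference)
  glob <- paste(as.character(reference), collapse = spacer)
  code <- encode_dna(glob)
  offsets <- cumsum(c(0L, head(lens + 40L, -1L)))  # global 0-based chrom starts

  n <- length(code)
  npos <- n - k + 1L
  key <- numeric(npos)
  pw <- 4^((k - 1L):0L)
  for (j in seq_len(k)) {
    key <- key + (code[j:(npos + j - 1L)] - 1L) * pw[j]
  }
  bad <- cumsum(code == 0L)
  valid <- (bad[k:n] - c(0L, bad[seq_len(npos - 1L)])) == 0L
  pos <- which(valid) - 1L            # 0-based global k-mer starts
  key <- key[valid]
  ord <- order(key, pos, method = "radix")
  structure(list(
    k = k, code = code, chroms = chroms, chrom_lens = lens,
    offsets = offsets,
    keys_sorted = key[ord], pos_sorted = pos[ord]
  ), class = "tag_index")
}

## Positions (0-based global) whose k-mer equals `key`.
index_lookup <- function(index, key) {
  hi <- findInterval(key, index$keys_sorted)
  lo <- findInterval(key - 0.5, index$keys_sorted) + 1L
  if (hi < lo) return(integer(0))
  index$pos_sorted[lo:hi]
}

## global 0-based position -> (chrom, local 0-based position)
global_to_local <- function(index, gpos) {
  ci <- findInterval(gpos, index$offsets)
  data.table(chrom = index$chroms[ci], pos = gpos - index$offsets[ci])
}

#' Enumerate all ungapped placements of a tag
#'
#' Seed-and-verify: every placement of `seq` (either strand) with at most
#' `max_mm` mismatches against the reference is returned. 'N' in the
#' reference mismatches every tag base.
#'
#' @param seq Tag sequence (character scalar, no 'N').
#' @param index A [build_index()] object.
#' @param max_mm Maximum mismatches (default 2).
#' @return `data.table` with `gpos` (0-based global), `strand` (`+`/`-`),
#'   `mism`; zero rows when unmapped.
#' @export
find_placements <- function(seq, index, max_mm = 2L) {
  k <- index$k
  len <- nchar(seq)
  n_seeds <- len %/% k
  if (n_seeds < max_mm + 1L) {
    stop("tag length ", len, " with seed length ", k,
         " cannot guarantee completeness for ", max_mm, " mismatches")
  }
  code_f <- encode_dna(seq)
  if (any(code_f == 0L)) return(data.table(gpos = integer(),
                                           strand = character(),
                                           mism = integer()))
  code_r <- 5L - rev(code_f)
  pw <- 4^((k - 1L):0L)
  seed_offsets <- (seq_len(max_mm + 1L) - 1L) * k    # 0-based tag offsets
  nref <- length(index$code)
  out <- list()
  for (st in c("+", "-")) {
    tc <- if (st == "+") code_f else code_r
    cand <- integer(0)
    for (o in seed_offsets) {
      key <- sum((tc[(o + 1L):(o + k)] - 1L) * pw)
      hits <- index_lookup(index, key)
      if (length(hits)) cand <- c(cand, hits - o)
    }
    cand <- unique(cand)
    cand <- cand[cand >= 0L & cand + len <= nref]
    if (length(cand)) {
      ## drop placements that would cross a chromosome boundary spacer
      ci <- findInterval(cand, index$offsets)
      cand <- cand[cand - index$offsets[ci] + len <= index$chrom_lens[ci]]
    }
    if (!length(cand)) next
    nc <- length(cand)
    idx <- rep(cand, each = len) + seq_len(len) - 1L + 1L
    cmp <- index$code[idx] != rep(tc, times = nc)
    mism <- colSums(matrix(cmp, nrow = len))
    ok <- mism <= max_mm
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.table(
        gpos = cand[ok], strand = st, mism = as.integer(mism[ok]))
    }
  }
  if (!length(out)) return(data.table(gpos = integer(), strand = character(),
                                      mism = integer()))
  rbindlist(out)
}

#' Align tags to an indexed reference
#'
#' For each tag, enumerates all placements with at most `max_mm` mismatches
#' (complete by the pigeonhole guarantee), reports the best one (ties broken
#' by lowest chromosome then coordinate, forward strand first), and assigns
#' the mapping-quality proxy:
#' \itemize{
#'   \item MQ 40 — unique best hit and no other placement within `max_mm`;
#'   \item MQ 25 — unique best hit but a second-best placement exists at
#'     strictly more mismatches;
#'   \item MQ 0 — two or more placements tied at the minimum.
#' }
#' The downstream stringent filter only consumes the threshold "MQ of at
#' least 40" and relative confidence, which this proxy preserves.
#'
#' @param sequences Character vector of tag sequences (N-free).
#' @param index A [build_index()] object.
#' @param max_mm Maximum mismatches (default 2).
#' @param chunk_size Tags verified per vectorised batch (performance knob;
#'   has no effect on results).
#' @return `data.table` with one row per input: `sequence`, `mapped`,
#'   `chrom`, `pos` (0-based), `strand`, `n_mismatches`, `n_best_hits`,
#'   `mapping_quality`.
#' @export
align_tags <- function(sequences, index, max_mm = 2L, chunk_size = 1024L) {
  n <- length(sequences)
  empty <- data.table(sequence = character(), mapped = logical(),
                      chrom = character(), pos = integer(),
                      strand = character(), n_mismatches = integer(),
                      n_best_hits = integer(), mapping_quality = integer())
  if (n == 0L) return(empty)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("tags must have uniform length")
  k <- index$k
  n_seeds <- max_mm + 1L
  if (len %/% k < n_seeds) {
    stop("tag length ", len, " with seed length ", k,
         " cannot guarantee completeness for ", max_mm, " mismatches")
  }
  tm <- matrix(.code_map[utf8ToInt(paste(sequences, collapse = ""))],
               ncol = len, byrow = TRUE)
  has_n <- rowSums(tm == 0L) > 0L
  pw <- 4^((k - 1L):0L)
  seed_off <- (seq_len(n_seeds) - 1L) * k
  nref <- length(index$code)
  refcode <- index$code

  out_chunks <- list()
  todo <- which(!has_n)
  chunks <- split(todo, ceiling(seq_along(todo) / chunk_size))
  for (chunk in chunks) {
    cm_f <- tm[chunk, , drop = FALSE]
    cm_r <- 5L - cm_f[, len:1L, drop = FALSE]
    m <- length(chunk)
    hits_all <- list()
    for (st in c("+", "-")) {
      M <- if (st == "+") cm_f else cm_r
      Mv <- as.vector(M)               # column-major for fast (row, j) access
      cand_row <- integer(0); cand_pos <- integer(0)
      for (o in seed_off) {
        key <- as.vector((M[, (o + 1L):(o + k), drop = FALSE] - 1L) %*% pw)
        hi <- findInterval(key, index$keys_sorted)
        lo <- findInterval(key - 0.5, index$keys_sorted) + 1L
        cnt <- pmax(hi - lo + 1L, 0L)
        if (sum(cnt) == 0L) next
        idx <- sequence(cnt) + rep(lo - 1L, cnt)
        cand_row <- c(cand_row, rep(seq_len(m), cnt))
        cand_pos <- c(cand_pos, index$pos_sorted[idx] - o)
      }
      if (!length(cand_row)) next
      ## dedupe (tag, position) pairs arriving via multiple seeds
      keydup <- cand_row * (nref + len + 1) + cand_pos
      keep <- !duplicated(keydup)
      cand_row <- cand_row[keep]; cand_pos <- cand_pos[keep]
      ## bounds and chromosome-boundary filtering
      ok <- cand_pos >= 0L & cand_pos + len <= nref
      cand_row <- cand_row[ok]; cand_pos <- cand_pos[ok]
      if (length(cand_pos)) {
        ci <- findInterval(cand_pos, index$offsets)
        ok <- cand_pos - index$offsets[ci] + len <= index$chrom_lens[ci]
        cand_row <- cand_row[ok]; cand_pos <- cand_pos[ok]
      }
      if (!length(cand_pos)) next
      ## Hamming verification with periodic pruning (mism only grows in j)
      mism <- integer(length(cand_pos))
      for (j in seq_len(len)) {
        mism <- mism + (refcode[cand_pos + j] != Mv[(j - 1L) * m + cand_row])
        if (j %% k == 0L && j < len) {
          keep <- mism <= max_mm
          if (!all(keep)) {
            cand_row <- cand_row[keep]; cand_pos <- cand_pos[keep]
            mism <- mism[keep]
          }
          if (!length(cand_pos)) break
        }
      }
      keep <- mism <= max_mm
      if (any(keep)) {
        hits_all[[st]] <- data.table(row = cand_row[keep],
                                     gpos = cand_pos[keep],
                                     strand = st,
                                     mism = as.integer(mism[keep]))
      }
    }
    if (length(hits_all)) {
      h <- rbindlist(hits_all)
      h[, row := chunk[row]]
      out_chunks[[length(out_chunks) + 1L]] <- h
    }
  }

  res <- data.table(sequence = sequences, mapped = FALSE,
                    chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, n_mismatches = NA_integer_,
                    n_best_hits = NA_integer_, mapping_quality = NA_integer_)
  if (length(out_chunks)) {
    h <- rbindlist(out_chunks)
    ## representative: fewest mismatches, then lowest coordinate, '+' first
    setorder(h, row, mism, gpos, strand)
    agg <- h[, list(gpos = gpos[1L], strand = strand[1L], best = mism[1L],
                    n_best = sum(mism == mism[1L]),
                    has_second = any(mism > mism[1L])), by = row]
    loc <- global_to_local(index, agg$gpos)
    mq <- ifelse(agg$n_best > 1L, 0L, ifelse(agg$has_second, 25L, 40L))
    res[agg$row, `:=`(mapped = TRUE, chrom = loc$chrom, pos = loc$pos,
                      strand = agg$strand, n_mismatches = agg$best,
                      n_best_hits = agg$n_best,
                      mapping_quality = as.integer(mq))]
  }
  res
}

#' @rdname align_tags
#' @param seq A single tag sequence.
#' @export
align_tag <- function(seq, index, max_mm = 2L) {
  align_tags(seq, index, max_mm)
}

#' Percentage of unique tags that align
#'
#' @param alignments Output of [align_tags()].
#' @return Percentage of (N-free) tags mapped, or `NA` for empty input.
#' @export
alignment_rate <- function(alignments) {
  if (nrow(alignments) == 0L) return(NA_real_)
  100 * sum(alignments$mapped) / nrow(alignments)
}

#' Write alignments to a tab-separated file
#'
#' Minimal declared format: tag sequence, chromosome, 1-based position,
#' strand, mismatches, best-hit count, mapping quality, read count.
#'
#' @param alignments Output of [align_tags()], optionally with a
#'   `read_count` column merged in.
#' @param path Output path.
#' @param header Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, header = NULL) {
  out <- as.data.table(alignments)[mapped == TRUE]
  df <- data.frame(
    tag = out$sequence, chrom = out$chrom, pos = out$pos + 1L,
    strand = out$strand, mismatches = out$n_mismatches,
    best_hits = out$n_best_hits, MQ = out$mapping_quality,
    read_count = if ("read_count" %in% names(out)) out$read_count else 1L
  )
  write_report_tsv(df, path, header)
}
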