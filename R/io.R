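## Shared readers/writers for the standard formats the pipeline touches.
## Conventions: all intervals are 0-based half-open internally ([start, end));
## user-facing report files are 1-based. FASTQ qualities are Sanger Phred+33.

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that tolerates CRLF
#' line endings and reduces headers to the first whitespace-delimited token.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence names in ", path)
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file into a table
#'
#' @param path Path to an uncompressed FASTQ file (Phred+33 qualities).
#' @return A `data.table` with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.table(id = character(), sequence = character(),
                      quality = character()))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ (", path, "): ", n,
         " lines is not a multiple of 4; last complete record ends at line ",
         4L * (n %/% 4L))
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): record ", bad[1L], " at line ",
         4L * (bad[1L] - 1L) + 1L, " does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): record ", bad[1L],
         " separator line is not '+'")
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): record ", bad[1L], " at line ",
         4L * (bad[1L] - 1L) + 1L, " has sequence length ",
         nchar(seqs[bad[1L]]), " but quality length ", nchar(quals[bad[1L]]))
  }
  data.table(id = sub("^@", "", ids), sequence = seqs, quality = quals)
}

#' Write reads to FASTQ
#'
#' @param reads A data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Only the first three columns are used. BED is 0-based half-open, matching
#' the package's internal convention, so coordinates pass through unchanged.
#'
#' @param path Path to a BED file.
#' @return A `data.table` with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(data.table(chrom = character(),
                                        start = integer(), end = integer()))
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = list(character = 1))
  if (ncol(x) < 3L) stop("BED file ", path, " has fewer than 3 columns")
  bed <- data.table(chrom = as.character(x[[1L]]),
                    start = as.integer(x[[2L]]),
                    end = as.integer(x[[3L]]))
  bad <- which(!(bed$end > bed$start))
  if (length(bad)) {
    stop("invalid BED interval at line ", bad[1L], " of ", path,
         ": end (", bed$end[bad[1L]], ") must exceed start (",
         bed$start[bad[1L]], ")")
  }
  bad <- which(bed$start < 0L)
  if (length(bad)) stop("negative start at line ", bad[1L], " of ", path)
  bed
}

#' Write intervals to BED
#'
#' @param bed A data.frame with columns `chrom`, `start`, `end`; extra columns
#'   are appended in order (e.g. name/score fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Convert a 0-based half-open interval table to GRanges (1-based closed).
bed_to_granges <- function(bed) {
  if (is.null(bed) || nrow(bed) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
}

## Per-position overlap width of 0-based intervals `q` with interval set `s`,
## both data.frames with chrom/start/end. Returns integer vector along q rows.
interval_overlap_bp <- function(q, s) {
  if (is.null(s) || nrow(s) == 0L || nrow(q) == 0L) {
    return(integer(nrow(q)))
  }
  qg <- bed_to_granges(q)
  sg <- GenomicRanges::reduce(bed_to_granges(s))
  hits <- GenomicRanges::findOverlaps(qg, sg)
  ov <- IRanges::pintersect(qg[S4Vectors::queryHits(hits)],
                            sg[S4Vectors::subjectHits(hits)])
  w <- integer(nrow(q))
  tab <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
  w[as.integer(names(tab))] <- as.integer(tab)
  w
}

## Set difference of 0-based interval tables: parts of `a` not covered by `b`.
interval_subtract <- function(a, b) {
  if (is.null(b) || nrow(b) == 0L || nrow(a) == 0L) {
    return(as.data.table(a)[, list(chrom, start, end)])
  }
  d <- GenomicRanges::setdiff(GenomicRanges::reduce(bed_to_granges(a)),
                              GenomicRanges::reduce(bed_to_granges(b)))
  data.table(chrom = as.character(GenomicRanges::seqnames(d)),
             start = BiocGenerics::start(d) - 1L,
             end = BiocGenerics::end(d))
}

## TRUE for each 0-based position covered by the interval set.
positions_in_intervals <- function(chrom, pos, s) {
  if (is.null(s) || nrow(s) == 0L || length(pos) == 0L) {
    return(logical(length(pos)))
  }
  q <- data.table(chrom = chrom, start = pos, end = pos + 1L)
  interval_overlap_bp(q, s) > 0L
}

#' Write a tab-separated report with provenance header lines
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
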