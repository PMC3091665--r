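## In-silico restriction digestion, fragment size selection, terminal tag
## extraction, and the enzyme-evaluation metric panel.
##
## All seven blunt 4-cutters considered for RRL construction (Acc II, Hae III,
## Rsa I, Dpn I, Alu I, CviR I, CviJ I) have IUPAC-palindromic recognition
## sites, so single-strand scanning of the forward strand is sufficient; the
## constructor enforces palindromicity rather than risk silent undercounting
## for a non-palindromic pattern.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

## Reverse complement of an IUPAC pattern (set-wise).
iupac_revcomp <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

## Expand an IUPAC pattern to a character-class regular expression.
## Used by tests as an independent scanning oracle; exported for reuse.
#' @rdname scan_cut_positions
#' @export
iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Define a blunt-cutting restriction enzyme
#'
#' A recognition pattern in IUPAC code together with the offset of its blunt
#' cut from the pattern start. The pattern must be its own reverse complement
#' under IUPAC expansion: digestion scans the forward strand only, which is
#' exact for palindromic sites and would miscount otherwise.
#'
#' @param name Enzyme name.
#' @param recognition Recognition site in IUPAC code (typically 4 bp).
#' @param cut_offset Cut position in bases from the pattern start
#'   (`0 <= cut_offset <= nchar(recognition)`).
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("CviRI", "TGCA", 2)   # TG^CA
#' @export
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  cut_offset <- as.integer(cut_offset)
  chars <- strsplit(recognition, "")[[1L]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop("enzyme ", name, ": '", bad[1L], "' is not an IUPAC nucleotide code")
  }
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("enzyme ", name, ": cut_offset must be in [0, ", nchar(recognition), "]")
  }
  if (iupac_revcomp(recognition) != recognition) {
    stop("enzyme ", name, ": recognition site ", recognition,
         " is not IUPAC-palindromic; forward-strand scanning would miscount")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  site <- x$recognition
  cat(sprintf("<enzyme_spec> %s  %s^%s\n", x$name,
              substr(site, 1, x$cut_offset),
              substr(site, x$cut_offset + 1, nchar(site))))
  invisible(x)
}

#' Load a table of enzyme definitions
#'
#' @param path TSV file with header columns `name`, `recognition`,
#'   `cut_offset`.
#' @return A named list of [enzyme_spec()] objects.
#' @export
load_enzyme_table <- function(path) {
  if (!file.exists(path)) stop("enzyme table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(tab))) {
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate enzyme name in ", path, ": ",
         tab$name[duplicated(tab$name)][1L])
  }
  specs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    specs[[i]] <- tryCatch(
      enzyme_spec(tab$name[i], tab$recognition[i], tab$cut_offset[i]),
      error = function(e) stop("enzyme table row ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  stats::setNames(specs, tab$name)
}

#' Bundled enzyme panel
#'
#' The seven commercially available blunt-end 4-cutters evaluated for
#' reduced-representation library design.
#'
#' @return A named list of [enzyme_spec()] objects.
#' @export
default_enzyme_panel <- function() {
  load_enzyme_table(system.file("extdata", "enzymes.tsv", package = "rrsnp"))
}

#' Scan a sequence for restriction cut positions
#'
#' Finds every occurrence of the recognition site on the forward strand
#' (sufficient for palindromic sites) and returns the 0-based coordinates of
#' the blunt cuts. Overlapping occurrences each produce a cut; duplicate cut
#' coordinates from degenerate patterns are collapsed. `N` never matches.
#'
#' @param seq A character scalar or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @param enzyme An [enzyme_spec()].
#' @param pattern For `iupac_to_regex`, an IUPAC pattern string.
#' @return Strictly increasing integer vector of 0-based cut coordinates
#'   (a cut at `c` separates `seq[1..c]` from `seq[(c+1)..]`).
#' @examples
#' scan_cut_positions("AAATGCAAAA", enzyme_spec("CviRI", "TGCA", 2))  # 5
#' @export
scan_cut_positions <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (!methods::is(seq, "DNAString")) {
    seq <- Biostrings::DNAString(as.character(seq))
  }
  if (length(seq) < nchar(enzyme$recognition)) return(integer(0))
  m <- Biostrings::matchPattern(enzyme$recognition, seq, fixed = "subject")
  starts0 <- BiocGenerics::start(m) - 1L   # 0-based site starts
  cuts <- sort(unique(starts0 + enzyme$cut_offset))
  ## cuts at the very ends of the sequence do not create new fragments
  cuts[cuts > 0L & cuts < length(seq)]
}

#' Digest a genome in silico
#'
#' Cuts every chromosome at each recognition site and returns the resulting
#' fragment partition: the intervals between consecutive cuts plus the two
#' terminal pieces. Per chromosome the fragments are disjoint, sorted, and
#' tile the sequence completely.
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param enzyme An [enzyme_spec()].
#' @param sequences If `TRUE` (default), include the fragment sequences.
#' @return A `data.table` with columns `fragment_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `terminal`, `selected` (initialised
#'   `FALSE`), and optionally `sequence`.
#' @export
digest <- function(genome, enzyme, sequences = TRUE) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("genome is empty")
  per_chrom <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    cuts <- scan_cut_positions(s, enzyme)
    bounds <- c(0L, cuts, length(s))
    n <- length(bounds) - 1L
    data.table(
      chrom = ch,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      terminal = c(TRUE, rep(FALSE, max(n - 2L, 0L)), if (n > 1L) TRUE)
    )
  })
  frags <- rbindlist(per_chrom)
  frags[, `:=`(length = end - start, selected = FALSE)]
  frags[, fragment_id := sprintf("%s:%d-%d", chrom, start, end)]
  if (sequences) {
    frags[, sequence := fragment_sequences(genome, .SD)]
  }
  data.table::setcolorder(
    frags, c("fragment_id", "chrom", "start", "end", "length",
             "terminal", "selected"))
  frags[]
}

## Extract fragment sequences for a coordinate table.
fragment_sequences <- function(genome, fragments) {
  genome <- as_genome(genome)
  out <- character(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    i <- which(fragments$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = fragments$start[i] + 1L,
                           end = fragments$end[i])
    out[i] <- as.character(v)
  }
  out
}

## Coerce character vectors to DNAStringSet; pass DNAStringSet through.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (methods::is(genome, "DNAString")) {
    return(Biostrings::DNAStringSet(stats::setNames(list(genome), "seq")))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet or named character vector")
}

#' Size-select fragments
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (both bounds
#' inclusive) and marks them `selected`. Order is preserved; re-running on
#' the output is a no-op.
#'
#' @param fragments Fragment table from [digest()].
#' @param min_len,max_len Inclusive length bounds in bp (default 70–200,
#'   the size window excised from the gel).
#' @return The selected subset of `fragments` with `selected = TRUE`.
#' @export
size_select <- function(fragments, min_len = 70L, max_len = 200L) {
  if (min_len > max_len) stop("min_len (", min_len, ") exceeds max_len (",
                              max_len, ")")
  out <- fragments[fragments$length >= min_len & fragments$length <= max_len, ]
  out$selected <- rep(TRUE, nrow(out))
  out
}

#' Extract terminal tags from fragments
#'
#' Each fragment yields a 5' tag (first `tag_len` bases) and a 3' tag (last
#' `tag_len` bases), both reported in reference orientation. Fragments
#' shorter than `tag_len` collapse to a single whole-fragment tag, flagged
#' with `collapsed = TRUE`.
#'
#' @param fragments Fragment table from [digest()] / [size_select()].
#' @param tag_len Tag length in bp (default 33, the sequenced read length).
#' @param genome Optional genome; when supplied a `sequence` column is added.
#' @return A `data.table` with columns `tag_id`, `fragment_id`, `chrom`,
#'   `start`, `end`, `side` (`"5p"`/`"3p"`), `collapsed`, and optionally
#'   `sequence`.
#' @export
extract_tags <- function(fragments, tag_len = 33L, genome = NULL) {
  tag_len <- as.integer(tag_len)
  ## at length == tag_len the two terminal tags coincide: collapse to one
  short <- fragments$length <= tag_len
  five <- data.table(
    fragment_id = fragments$fragment_id,
    chrom = fragments$chrom,
    start = fragments$start,
    end = pmin(fragments$start + tag_len, fragments$end),
    side = "5p",
    collapsed = short
  )
  three <- data.table(
    fragment_id = fragments$fragment_id[!short],
    chrom = fragments$chrom[!short],
    start = pmax(fragments$end[!short] - tag_len, fragments$start[!short]),
    end = fragments$end[!short],
    side = "3p",
    collapsed = FALSE
  )
  tags <- rbindlist(list(five, three))
  setorder(tags, chrom, start, side)
  tags[, id := sprintf("%s:%d-%d:%s", chrom, start, end, side)]
  setnames(tags, "id", "tag_id")
  data.table::setcolorder(tags, c("tag_id", "fragment_id"))
  if (!is.null(genome)) {
    tags[, sequence := fragment_sequences(genome, .SD)]
  }
  tags[]
}

#' Fraction of a tag footprint covered by repeat annotation
#'
#' @param tags Tag table from [extract_tags()].
#' @param repeat_intervals Repeat annotation as a `chrom`/`start`/`end` table
#'   (0-based half-open, e.g. from [read_bed()]), or `NULL`.
#' @return Numeric vector in `[0, 1]`, one value per tag.
#' @export
tag_repeat_fraction <- function(tags, repeat_intervals) {
  if (nrow(tags) == 0L) return(numeric(0))
  ov <- interval_overlap_bp(tags, repeat_intervals)
  ov / (tags$end - tags$start)
}

#' Enzyme-evaluation metric arithmetic
#'
#' The metric panel used to compare enzymes for reduced-representation
#' library design, computed from a digest's summary counts:
#' \describe{
#'   \item{complexity_reduction_pct}{`100 * total_selected_length /
#'     genome_length` — the fraction of the genome carried into the library.}
#'   \item{coverage_per_run}{`run_output_bp / total_selected_length` — fold
#'     coverage of the selected portion from one sequencing run.}
#'   \item{tag_density_per_mbp}{`2 * n_selected / (genome_length / 1e6)` —
#'     sequenced tags per Mbp of genome.}
#'   \item{predicted_snps}{`2 * tag_len * n_selected / snp_rate_bp` —
#'     expected SNPs in the sequenced tag bases at the genome-wide SNP rate.}
#'   \item{pct_selected_portion}{`100 * n_selected / n_total`.}
#' }
#'
#' @param n_total Total fragment count from the digest.
#' @param n_selected Fragments in the size window.
#' @param total_selected_length Summed length (bp) of selected fragments.
#' @param genome_length Genome size in bp (default 1.1e9).
#' @param snp_rate_bp Bases per SNP between the parent genotypes
#'   (default 5000, i.e. 1 SNP / 5 kbp).
#' @param tag_len Sequenced tag length (default 33).
#' @param run_output_bp Usable bases from one sequencing run
#'   (default 1.9242e9).
#' @return A one-row `data.frame` of the metrics.
#' @export
digest_metrics <- function(n_total, n_selected, total_selected_length,
                           genome_length = 1.1e9, snp_rate_bp = 5000,
                           tag_len = 33L, run_output_bp = 1.9242e9) {
  if (n_selected == 0L) {
    warning("no fragments in the size window; ratio metrics reported as 0")
    return(data.frame(
      n_total_fragments = n_total, n_selected_fragments = 0L,
      total_selected_length = 0,
      complexity_reduction_pct = 0, coverage_per_run = 0,
      tag_density_per_mbp = 0, predicted_snps = 0, pct_selected_portion = 0
    ))
  }
  data.frame(
    n_total_fragments = n_total,
    n_selected_fragments = n_selected,
    total_selected_length = total_selected_length,
    complexity_reduction_pct = 100 * total_selected_length / genome_length,
    coverage_per_run = run_output_bp / total_selected_length,
    tag_density_per_mbp = 2 * n_selected / (genome_length / 1e6),
    predicted_snps = 2 * tag_len * n_selected / snp_rate_bp,
    pct_selected_portion = 100 * n_selected / n_total
  )
}

#' Full digest report for one enzyme
#'
#' Applies size selection to a digest, computes the metric panel of
#' [digest_metrics()], and adds the repeat accounting: a selected fragment
#' counts as repetitive when either of its terminal tags overlaps the repeat
#' annotation by at least `repeat_threshold` of its bases.
#' `pct_repetitive_selected` is `100 * n_repetitive_selected / n_selected`
#' (an explicitly defined percentage; see the methods vignette).
#'
#' @param fragments Full fragment table from [digest()] (one enzyme).
#' @param genome_length Genome size in bp.
#' @param repeat_intervals Repeat annotation table or `NULL`.
#' @param enzyme_name Name stamped into the report row.
#' @param min_len,max_len Size-selection window (default 70–200 bp).
#' @param repeat_threshold Minimum repeat-overlap fraction of a terminal tag
#'   for the fragment to count as repetitive (default 0.5).
#' @inheritParams digest_metrics
#' @return A one-row `data.frame`: enzyme name, the [digest_metrics()] panel,
#'   `n_repetitive_selected` and `pct_repetitive_selected`.
#' @export
compute_digest_report <- function(fragments, genome_length,
                                  repeat_intervals = NULL,
                                  enzyme_name = "enzyme",
                                  min_len = 70L, max_len = 200L,
                                  tag_len = 33L, snp_rate_bp = 5000,
                                  run_output_bp = 1.9242e9,
                                  repeat_threshold = 0.5) {
  sel <- size_select(fragments, min_len, max_len)
  metrics <- digest_metrics(
    n_total = nrow(fragments), n_selected = nrow(sel),
    total_selected_length = sum(sel$length),
    genome_length = genome_length, snp_rate_bp = snp_rate_bp,
    tag_len = tag_len, run_output_bp = run_output_bp
  )
  n_rep <- 0L
  if (nrow(sel) > 0L && !is.null(repeat_intervals) &&
      nrow(repeat_intervals) > 0L) {
    tags <- extract_tags(sel, tag_len = tag_len)
    frac <- tag_repeat_fraction(tags, repeat_intervals)
    rep_frag <- unique(tags$fragment_id[frac >= repeat_threshold])
    n_rep <- length(rep_frag)
  }
  cbind(
    data.frame(enzyme = enzyme_name),
    metrics,
    data.frame(
      n_repetitive_selected = n_rep,
      pct_repetitive_selected = if (nrow(sel) > 0L) 100 * n_rep / nrow(sel) else 0
    )
  )
}
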