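## Shared fixtures and independent oracles. Everything is generated in code;
## no binary fixtures.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Independent cut-position oracle: IUPAC -> regex character classes, scanned
## with a zero-width lookahead so overlapping occurrences all count. Shares no
## code path with scan_cut_positions (which uses Biostrings matchPattern).
oracle_scan <- function(seq, enzyme) {
  rx <- paste0("(?=", iupac_to_regex(enzyme$recognition), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  cuts <- sort(unique(as.integer(m) - 1L + enzyme$cut_offset))
  cuts[cuts > 0L & cuts < nchar(seq)]
}

## Exhaustive placement oracle via Biostrings matchPattern (max.mismatch):
## all ungapped placements of `tag` on both strands of a named sequence set.
oracle_placements <- function(tag, ref, max_mm = 2L) {
  out <- list()
  for (ch in names(ref)) {
    s <- Biostrings::DNAString(ref[[ch]])
    for (st in c("+", "-")) {
      q <- if (st == "+") tag else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
      m <- Biostrings::matchPattern(q, s, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m)) {
        mm <- vapply(seq_along(m), function(i) {
          sum(strsplit(as.character(m[[i]]), "")[[1]] !=
                strsplit(q, "")[[1]])
        }, integer(1))
        keep <- mm <= max_mm   # matchPattern can return shifted edge hits
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, pos = BiocGenerics::start(m)[keep] - 1L,
            strand = st, mism = mm[keep])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), mism = integer()))
  }
  do.call(rbind, out)
}

## Brute-force 10-bp window purge oracle: enumerate every window start.
oracle_window_keep <- function(pos, window = 10L, max_per_window = 2L) {
  keep <- rep(TRUE, length(pos))
  if (!length(pos)) return(keep)
  for (w in (min(pos) - window + 1L):max(pos)) {
    inw <- pos >= w & pos < w + window
    if (sum(inw) > max_per_window) keep[inw] <- FALSE
  }
  keep
}

## A tiny deterministic two-chromosome reference for alignment tests.
make_test_ref <- function(n1 = 30000L, n2 = 20000L, seed = 11L) {
  set.seed(seed)
  c(chrA = rand_dna(n1), chrB = rand_dna(n2))
}

## Memoised full demo run (1 Mb, seed fixed a priori) shared by the pipeline
## smoke test and the acceptance checks.
.demo_cache <- new.env(parent = emptyenv())
demo_run <- function() {
  if (is.null(.demo_cache$res)) {
    .demo_cache$outdir <- file.path(tempdir(), "rrsnp-demo")
    .demo_cache$res <- run_pipeline(demo_config(seed = 101),
                                    .demo_cache$outdir, quiet = TRUE)
  }
  .demo_cache$res
}
demo_outdir <- function() {
  demo_run()
  .demo_cache$outdir
}

## Small error-free study used by several calling tests.
.small_cache <- new.env(parent = emptyenv())
small_clean_run <- function() {
  if (is.null(.small_cache$res)) {
    cfg <- pipeline_config(sim = sim_config(
      genome_length = 300000, n_chromosomes = 1L, duplication_count = 2L,
      base_error_rate = 0, n_rate = 0, seed = 7L))
    .small_cache$res <- run_pipeline(cfg, file.path(tempdir(), "rrsnp-small"),
                                     quiet = TRUE)
  }
  .small_cache$res
}
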