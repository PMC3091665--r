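## End-to-end orchestration: simulate -> digest/report -> align -> call ->
## survey, with provenance-stamped artifacts and deterministic outputs under
## a fixed seed.

#' Pipeline configuration
#'
#' One document holding every stage's parameters. Defaults reproduce the
#' package's reference study design: CviRI digestion, 70–200 bp size
#' selection, 33-bp tags, 2-mismatch alignment, the lenient (depth 3) and
#' stringent (depth 10 / MQ 40 / consensus 10 / 3-bp indel flank) filter
#' ladders, 10-kbp survey windows.
#'
#' @param sim A [sim_config()] for the synthetic study.
#' @param enzyme Enzyme name, looked up in `enzyme_table`.
#' @param enzyme_table Path to an enzyme TSV, or `NULL` for the bundled
#'   panel.
#' @param size_range Inclusive fragment size window in bp.
#' @param max_mm Alignment mismatch tolerance.
#' @param lenient,stringent Named lists of filter parameters (see
#'   [filter_lenient()], [filter_stringent()]).
#' @param flank Flanking-context length for assay design (bp).
#' @param survey_window Survey window width (bp).
#' @param high_coverage_threshold Read-count split for repeat enrichment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            enzyme = "CviRI",
                            enzyme_table = NULL,
                            size_range = c(70L, 200L),
                            max_mm = 2L,
                            lenient = list(min_depth = 3L, window = 10L,
                                           max_per_window = 2L),
                            stringent = list(min_depth = 10L,
                                             indel_flank = 3L,
                                             min_mq = 40L,
                                             min_consensus = 10L),
                            flank = 60L,
                            survey_window = 10000L,
                            high_coverage_threshold = 200L) {
  structure(list(
    sim = sim, enzyme = enzyme, enzyme_table = enzyme_table,
    size_range = as.integer(size_range), max_mm = as.integer(max_mm),
    lenient = lenient, stringent = stringent, flank = as.integer(flank),
    survey_window = as.integer(survey_window),
    high_coverage_threshold = as.integer(high_coverage_threshold)
  ), class = "pipeline_config")
}

#' The bundled demo configuration
#'
#' A 1-Mbp two-chromosome synthetic study under the default generator
#' settings; `...` overrides [sim_config()] fields (e.g. a smaller
#' `genome_length` for quick runs).
#'
#' @param seed Root seed.
#' @param ... Passed to [sim_config()].
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  pipeline_config(sim = sim_config(seed = seed, ...))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- if (!is.null(y$sim)) y$sim else list()
  y$sim <- do.call(sim_config, simargs)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path)
  invisible(path)
}

## Stable md5 of the canonical JSON form of a config.
config_hash <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(x[order(names(x))], strip) else unclass(x)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip(unclass(config)), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Footprints of selected terminal tags, with uniqueness flags
#'
#' Digests the reference, size-selects, extracts terminal tags and aligns
#' each tag sequence back to the reference; a footprint is unique when its
#' tag places once with no second placement within the mismatch tolerance
#' (mapping quality 40 under the package's proxy).
#'
#' @param reference Reference genome.
#' @param enzyme An [enzyme_spec()].
#' @param size_range Inclusive size window.
#' @param tag_len Tag length.
#' @param max_mm Mismatch tolerance used for the uniqueness test.
#' @param index Optional prebuilt [build_index()] of `reference`.
#' @return Tag table with a `unique` flag.
#' @export
unique_tag_footprints <- function(reference, enzyme,
                                  size_range = c(70L, 200L), tag_len = 33L,
                                  max_mm = 2L, index = NULL) {
  reference <- as_genome(reference)
  frags <- digest(reference, enzyme, sequences = FALSE)
  sel <- size_select(frags, size_range[1L], size_range[2L])
  tags <- extract_tags(sel, tag_len = tag_len, genome = reference)
  if (is.null(index)) index <- build_index(reference)
  aln <- align_tags(tags$sequence, index, max_mm = max_mm)
  tags[, unique := aln$mapped & aln$mapping_quality == 40L]
  tags[]
}

#' Score variant recovery against the simulation truth
#'
#' Recall and precision of a call set inside an evaluation region (typically
#' the unique selected-tag footprints). The recall denominator is restricted
#' to truth SNPs that received at least one sequenced read of the
#' alternate-parent tag carrying them (`covered`): a variant with zero alt
#' reads is not interrogable by any caller and says nothing about one.
#'
#' @param calls Candidate table (e.g. stringent tier).
#' @param truth Truth table from [make_parent_genomes()].
#' @param region Interval table (`chrom`/`start`/`end`, 0-based) defining
#'   the evaluation region.
#' @param covered Logical vector along `truth` rows: variant had alt-read
#'   coverage. Default: all `TRUE`.
#' @return List: `recall`, `precision`, `n_truth_region`, `n_truth_eval`,
#'   `n_calls_region`, `n_tp`.
#' @export
score_recovery <- function(calls, truth, region, covered = NULL) {
  truth <- as.data.table(truth)
  calls <- as.data.table(calls)
  if (is.null(covered)) covered <- rep(TRUE, nrow(truth))
  tsnp <- truth$type == "SNP"
  t_in <- tsnp & positions_in_intervals(truth$chrom, truth$pos, region)
  t_eval <- t_in & covered
  c_in <- if (nrow(calls)) {
    positions_in_intervals(calls$chrom, calls$pos, region)
  } else logical(0)
  key_t <- paste(truth$chrom, truth$pos, truth$alt)
  key_c <- if (nrow(calls)) paste(calls$chrom, calls$pos, calls$alt)
           else character(0)
  tp_call <- c_in & key_c %in% key_t[t_in]
  found_eval <- key_t[t_eval] %in% key_c[c_in]
  list(
    recall = if (sum(t_eval) > 0L) sum(found_eval) / sum(t_eval) else NA_real_,
    precision = if (sum(c_in) > 0L) sum(tp_call) / sum(c_in) else NA_real_,
    n_truth_region = sum(t_in),
    n_truth_eval = sum(t_eval),
    n_calls_region = sum(c_in),
    n_tp = sum(tp_call)
  )
}

#' Run the full pipeline on a synthetic study
#'
#' Executes simulate → digest/report → align → call → survey and writes the
#' artifact set (`reference.fa`, `alternate.fa`, `repeats.bed`, `truth.tsv`,
#' `reads.fastq`, `digest_report.tsv`, `aln.tsv`, `calls.vcf`, `flanks.tsv`,
#' `filter_audit.tsv`, `survey_windows.tsv`, `summary.json`) into `outdir`,
#' each stamped with the configuration hash and seed. Identical
#' configurations produce byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress stage progress messages (written to stderr).
#' @return Invisibly, a list of in-memory results: `sim`, `digest_report`,
#'   `collapse_summary`, `alignments`, `alignment_rate`, `candidates`
#'   (tier-annotated), `lenient`, `stringent`, `stringent_cross`, `survey`,
#'   `recovery`, `paralog`, `coverage_fit`, `paths`, `config_hash`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[rrsnp] ", ...)
  hash <- config_hash(config)
  stamp <- c(paste0("config_md5=", hash),
             paste0("seed=", config$sim$seed))
  panel <- if (is.null(config$enzyme_table)) default_enzyme_panel()
           else load_enzyme_table(config$enzyme_table)
  if (!config$enzyme %in% names(panel)) {
    stop("enzyme '", config$enzyme, "' not in enzyme table")
  }
  enzyme <- panel[[config$enzyme]]
  pth <- function(f) file.path(outdir, f)

  say("simulate: generating parent genomes (",
      format(config$sim$genome_length, big.mark = ","), " bp)")
  sim <- make_parent_genomes(config$sim)
  write_fasta(sim$reference, pth("reference.fa"))
  write_fasta(sim$alternate, pth("alternate.fa"))
  write_bed(sim$repeats, pth("repeats.bed"))

  say("digest: ", enzyme$name, " evaluation report")
  frags <- digest(sim$reference, enzyme, sequences = FALSE)
  report <- compute_digest_report(
    frags, genome_length = sum(BiocGenerics::width(sim$reference)),
    repeat_intervals = sim$repeats, enzyme_name = enzyme$name,
    min_len = config$size_range[1L], max_len = config$size_range[2L],
    tag_len = config$sim$tag_len)
  write_report_tsv(report, pth("digest_report.tsv"), stamp)

  say("simulate: sequencing pooled tag reads")
  simreads <- simulate_tag_reads(sim$reference, sim$alternate, enzyme,
                                 size_range = config$size_range,
                                 config = config$sim, repeats = sim$repeats)
  write_fastq(simreads$reads, pth("reads.fastq"))

  say("align: collapsing ", nrow(simreads$reads), " reads")
  col <- collapse_unique(simreads$reads)
  index <- build_index(sim$reference)
  tag_in <- col$tags[has_N == FALSE]
  say("align: mapping ", nrow(tag_in), " unique tags")
  aln <- align_tags(tag_in$sequence, index, max_mm = config$max_mm)
  aln[, read_count := tag_in$read_count]
  aln[, quality := tag_in$quality]
  write_alignments(aln, pth("aln.tsv"), stamp)
  arate <- alignment_rate(aln)

  say("call: pileup and candidate calling")
  pileup <- build_pileup(aln, sim$reference)
  cand <- call_candidates(pileup)
  indels <- sim$truth[type != "SNP",
                      list(chrom, pos,
                           length = ifelse(type == "del", nchar(ref), 0L))]
  len <- do.call(filter_lenient,
                 c(list(cand, sim$repeats), config$lenient))
  stri <- do.call(filter_stringent, c(list(len, indels), config$stringent))
  cross <- cross_assembly_filter(stri, aln, sim$reference, sim$repeats,
                                 max_mm = config$max_mm)
  say("call: ", nrow(cand), " candidates, ", nrow(len), " lenient, ",
      nrow(stri), " stringent, ", nrow(cross), " after cross-assembly")

  tiered <- data.table::copy(cand)
  keyof <- function(x) paste(x$chrom, x$pos)
  tiered[keyof(tiered) %in% keyof(len), tier := "lenient"]
  tiered[keyof(tiered) %in% keyof(stri), tier := "stringent"]
  write_vcf(tiered, sim$reference, pth("calls.vcf"),
            extra_header = paste0("##", stamp))
  flanks <- extract_flanks(cross, sim$reference, flank = config$flank)
  write_report_tsv(flanks, pth("flanks.tsv"), stamp)

  la <- attr(len, "audit"); sa <- attr(stri, "audit")
  audit <- merge(la, sa, by = c("chrom", "pos", "ref", "alt"),
                 all.x = TRUE, suffixes = c("_lenient", "_stringent"))
  setorder(audit, chrom, pos)
  write_report_tsv(audit, pth("filter_audit.tsv"), stamp)

  say("survey: windows, correlations, coverage classes")
  ws <- window_stats(sim$reference, sim$repeats, aln,
                     window = config$survey_window)
  write_report_tsv(ws, pth("survey_windows.tsv"), stamp)
  enr <- high_coverage_repeat_enrichment(
    aln, sim$repeats, threshold = config$high_coverage_threshold,
    tag_len = config$sim$tag_len)
  hist3 <- coverage_histogram(col$tags$read_count)
  fit <- fit_gamma_overdispersion(simreads$tags$count)
  surv <- list(
    r_repeat_coverage = pearson_r(ws$repetitive_fraction, ws$read_count),
    r_gc_coverage = pearson_r(ws$gc_fraction, ws$read_count),
    enrichment = enr,
    pct_single_read = col$summary$pct_single_read,
    pct_multi_read = col$summary$pct_multi_read,
    pct_with_N = col$summary$pct_with_N,
    alignment_rate = arate,
    snp_read_positions = snp_read_position_distribution(
      len, aln, tag_len = config$sim$tag_len)
  )

  ## recovery vs truth inside unique selected-tag footprints
  say("score: recovery against spiked truth")
  fp <- unique_tag_footprints(sim$reference, enzyme,
                              size_range = config$size_range,
                              tag_len = config$sim$tag_len,
                              max_mm = config$max_mm, index = index)
  ## callable region: unique footprints minus repeat-annotated positions
  ## (the lenient ladder forbids calls at repeat positions by rule)
  region <- interval_subtract(fp[unique == TRUE, list(chrom, start, end)],
                              sim$repeats)
  alt_cov <- simreads$tags[parent == "alt" & count >= 1L,
                           list(chrom, start, end)]
  covered <- positions_in_intervals(sim$truth$chrom, sim$truth$alt_pos,
                                    alt_cov)
  ## scored on the stringent tier; the cross-assembly exclusion is a further
  ## step whose set size is reported separately
  recovery <- score_recovery(stri, sim$truth, region, covered)

  ## paralog accounting: lenient-tier calls inside duplication intervals
  dup_iv <- rbindlist(list(
    sim$duplications[, list(chrom, start = src_start, end = src_end)],
    sim$duplications[, list(chrom, start = dst_start, end = dst_end)]))
  paralog <- list(
    n_lenient_in_paralog = if (nrow(len))
      sum(positions_in_intervals(len$chrom, len$pos, dup_iv)) else 0L,
    n_stringent_in_paralog = if (nrow(stri))
      sum(positions_in_intervals(stri$chrom, stri$pos, dup_iv)) else 0L
  )

  truth_out <- flag_truth_in_footprints(sim$truth, fp)
  truth_out[, pos := pos + 1L]   # 1-based in the artifact
  write_report_tsv(truth_out[, list(chrom, pos, ref, alt, type,
                                    in_footprint)],
                   pth("truth.tsv"), stamp)

  summary <- list(
    config_md5 = hash, seed = config$sim$seed,
    enzyme = enzyme$name,
    n_reads = nrow(simreads$reads),
    n_unique_tags = col$summary$n_unique,
    pct_single_read = col$summary$pct_single_read,
    pct_multi_read = col$summary$pct_multi_read,
    pct_with_N = col$summary$pct_with_N,
    alignment_rate = arate,
    n_candidates = nrow(cand),
    n_lenient = nrow(len), n_stringent = nrow(stri),
    n_stringent_cross = nrow(cross),
    coverage_shape = fit$shape, coverage_mean = fit$mean,
    var_mean_ratio = fit$var_mean_ratio,
    r_repeat_coverage = surv$r_repeat_coverage,
    r_gc_coverage = surv$r_gc_coverage,
    pct_repetitive_above = enr$pct_repetitive_above,
    pct_repetitive_below = enr$pct_repetitive_below,
    recovery = recovery, paralog = paralog
  )
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    sim = sim, digest_report = report, collapse_summary = col$summary,
    unique_tags = col$tags, alignments = aln, alignment_rate = arate,
    pileup = pileup, candidates = tiered, lenient = len, stringent = stri,
    stringent_cross = cross, flanks = flanks, survey = surv,
    coverage_fit = fit, sim_tags = simreads$tags, recovery = recovery,
    paralog = paralog, footprints = fp, config_hash = hash,
    paths = vapply(c("reference.fa", "alternate.fa", "repeats.bed",
                     "truth.tsv", "reads.fastq", "digest_report.tsv",
                     "aln.tsv", "calls.vcf", "flanks.tsv",
                     "filter_audit.tsv", "survey_windows.tsv",
                     "summary.json"), pth, character(1))
  ))
}
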