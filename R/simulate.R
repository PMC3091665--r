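## Synthetic study generator: two parental genomes that differ by spiked SNPs
## and sparse short indels, an interspersed repeat structure with segmental
## duplications (paralog traps), and pooled 33-mer tag reads with
## Gamma-overdispersed, repeat-inflated coverage.
##
## RNG discipline: one root seed; every stage derives a named substream so
## that adding or reordering a stage never shifts another stage's draws.

BASES <- c("A", "C", "G", "T")

## Deterministic per-stage seed derivation (kept below 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

## Vectorised reverse complement for plain character sequences.
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Configuration for the synthetic study generator
#'
#' Defaults describe the study the package emulates: a repeat-rich plant
#' genome (~59% interspersed repeats), two inbred parents differing at
#' 1 SNP / 5,000 bp with sparse 1–3 bp indels, and pooled tag sequencing with
#' strongly overdispersed per-tag coverage (Gamma-mixed Poisson) inflated in
#' repetitive regions.
#'
#' @param genome_length Total genome size in bp across all chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param repeat_fraction Target fraction of the genome covered by repeat
#'   families (default 0.59).
#' @param repeat_monomer_lengths Lengths of the repeat family seed monomers.
#' @param repeat_divergence Per-copy substitution divergence of repeat copies
#'   from their family monomer (default 0.05).
#' @param duplication_count Number of segmental duplications (paralog pairs).
#' @param duplication_length Length of each duplicated segment in bp.
#' @param duplication_divergence Substitution divergence between the two
#'   copies of a duplication (default 0.01).
#' @param snp_rate Per-bp SNP rate between the parents (default 1/5000).
#' @param indel_rate Per-bp rate of 1–3 bp indels between the parents
#'   (default 2e-5).
#' @param mean_tag_coverage Mean reads per tag, \eqn{\mu}.
#' @param gamma_shape Shape \eqn{k} of the Gamma coverage multiplier
#'   (mean 1); per-tag counts are then negative binomial with
#'   \eqn{Var/mean = 1 + \mu/k}.
#' @param repeat_coverage_multiplier Coverage fold-inflation for tags whose
#'   footprint is repetitive (default 5).
#' @param base_error_rate Per-base substitution error rate in reads.
#' @param n_rate Per-base rate of 'N' base calls in reads.
#' @param tag_len Read/tag length in bp (default 33).
#' @param seed Root RNG seed; fixed seed gives byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 2L,
                       repeat_fraction = 0.59,
                       repeat_monomer_lengths = c(150L, 400L, 800L),
                       repeat_divergence = 0.05,
                       duplication_count = 5L,
                       duplication_length = 2000L,
                       duplication_divergence = 0.01,
                       snp_rate = 1 / 5000,
                       indel_rate = 2e-5,
                       mean_tag_coverage = 20,
                       gamma_shape = 1,
                       repeat_coverage_multiplier = 5,
                       base_error_rate = 0.001,
                       n_rate = 0.0009,
                       tag_len = 33L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    repeat_fraction = repeat_fraction,
    repeat_monomer_lengths = as.integer(repeat_monomer_lengths),
    repeat_divergence = repeat_divergence,
    duplication_count = as.integer(duplication_count),
    duplication_length = as.integer(duplication_length),
    duplication_divergence = duplication_divergence,
    snp_rate = snp_rate,
    indel_rate = indel_rate,
    mean_tag_coverage = mean_tag_coverage,
    gamma_shape = gamma_shape,
    repeat_coverage_multiplier = repeat_coverage_multiplier,
    base_error_rate = base_error_rate,
    n_rate = n_rate,
    tag_len = as.integer(tag_len),
    seed = as.integer(seed)
  )
  rates <- c("repeat_fraction", "repeat_divergence", "duplication_divergence",
             "snp_rate", "indel_rate", "base_error_rate", "n_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  }
  if (cfg$mean_tag_coverage <= 0) stop("mean_tag_coverage must be > 0")
  if (cfg$gamma_shape <= 0) stop("gamma_shape must be > 0")
  structure(cfg, class = "sim_config")
}

## Mutate a base vector at the given per-base substitution rate.
mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(BASES, b), 1L),
                     character(1))
  }
  x
}

#' Generate the two parental genomes, repeat annotation and variant truth
#'
#' Builds a reference genome with interspersed repeat families (each copy
#' diverged from its family monomer) and segmental duplications, then derives
#' the alternate parent by spiking SNPs and sparse short indels. Edits that
#' would collide (within 5 bp of an indel) are skipped. Duplications are
#' deliberately absent from the repeat annotation: they are the paralog traps
#' that produce false SNP calls at the lenient filter tier.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{reference, alternate}{[Biostrings::DNAStringSet] genomes.}
#'     \item{truth}{`data.table` of spiked variants: `chrom`, `pos`
#'       (0-based, reference), `alt_pos` (0-based, alternate coordinates),
#'       `ref`, `alt`, `type` (`SNP`/`ins`/`del`), `in_footprint`
#'       (`NA` until [flag_truth_in_footprints()]).}
#'     \item{repeats}{Repeat annotation, 0-based half-open `data.table`.}
#'     \item{duplications}{Paralog-pair table: source and copy intervals.}
#'   }
#' @export
make_parent_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrom_len <- as.integer(round(config$genome_length / config$n_chromosomes))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  ## --- family monomers (shared across chromosomes) -----------------------
  ## GC-balanced monomers: the coverage model has no GC effect by design, so
  ## repeat families must not smuggle a GC-coverage correlation in
  set.seed(stage_seed(config$seed, "monomers"))
  monomers <- lapply(config$repeat_monomer_lengths, function(len) {
    sample(rep(BASES, length.out = len))
  })

  ## --- reference backbone + repeats + duplications ------------------------
  set.seed(stage_seed(config$seed, "reference"))
  ref <- vector("list", length(chroms))
  names(ref) <- chroms
  rep_bed <- list()
  dup_tab <- list()
  per_family_bp <- config$repeat_fraction * chrom_len /
    max(length(monomers), 1L)
  for (ci in seq_along(chroms)) {
    x <- sample(BASES, chrom_len, replace = TRUE)
    iv <- list()
    for (fi in seq_along(monomers)) {
      mono <- monomers[[fi]]
      n_copies <- max(0L, as.integer(round(per_family_bp / length(mono))))
      if (n_copies == 0L) next
      starts <- sort(sample.int(chrom_len - length(mono), n_copies))
      for (s in starts) {
        copy <- mutate_bases(mono, config$repeat_divergence)
        x[s:(s + length(mono) - 1L)] <- copy
      }
      iv[[length(iv) + 1L]] <- data.table(
        chrom = chroms[ci], start = starts - 1L,
        end = starts - 1L + length(mono), family = fi)
    }
    rep_bed[[ci]] <- if (length(iv)) rbindlist(iv) else
      data.table(chrom = character(), start = integer(),
                 end = integer(), family = integer())
    ## segmental duplications: copy a source segment over a distant target
    n_dup <- config$duplication_count
    dl <- config$duplication_length
    if (n_dup > 0L && ci == 1L && chrom_len > 4L * dl) {
      dd <- vector("list", n_dup)
      for (d in seq_len(n_dup)) {
        repeat {
          src <- sample.int(chrom_len - dl, 1L)
          dst <- sample.int(chrom_len - dl, 1L)
          if (abs(dst - src) > 2L * dl) break
        }
        seg <- mutate_bases(x[src:(src + dl - 1L)],
                            config$duplication_divergence)
        x[dst:(dst + dl - 1L)] <- seg
        dd[[d]] <- data.table(chrom = chroms[ci],
                              src_start = src - 1L, src_end = src - 1L + dl,
                              dst_start = dst - 1L, dst_end = dst - 1L + dl)
      }
      dup_tab[[length(dup_tab) + 1L]] <- rbindlist(dd)
    }
    ref[[ci]] <- x
  }
  repeats <- rbindlist(rep_bed)
  setorder(repeats, chrom, start)
  duplications <- if (length(dup_tab)) rbindlist(dup_tab) else
    data.table(chrom = character(), src_start = integer(),
               src_end = integer(), dst_start = integer(),
               dst_end = integer())

  ## --- alternate parent: spike SNPs and indels ----------------------------
  set.seed(stage_seed(config$seed, "variants"))
  alt <- vector("list", length(chroms))
  names(alt) <- chroms
  truth <- list()
  for (ci in seq_along(chroms)) {
    x <- ref[[ci]]
    L <- length(x)
    snp_pos <- which(runif(L) < config$snp_rate)           # 1-based
    indel_pos <- which(runif(L) < config$indel_rate)
    ## skip collisions: indels too close to each other or to a SNP
    if (length(indel_pos) > 1L) {
      keep_i <- c(TRUE, diff(indel_pos) > 10L)
      indel_pos <- indel_pos[keep_i]
    }
    indel_pos <- indel_pos[indel_pos > 5L & indel_pos < L - 5L]
    if (length(snp_pos) && length(indel_pos)) {
      near <- vapply(snp_pos, function(p) any(abs(indel_pos - p) <= 5L),
                     logical(1))
      if (any(near)) {
        message("skipping ", sum(near), " spiked SNP(s) colliding with indels",
                " on ", chroms[ci])
        snp_pos <- snp_pos[!near]
      }
    }
    y <- x
    rows <- list()
    if (length(snp_pos)) {
      alt_base <- vapply(x[snp_pos], function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
      y[snp_pos] <- alt_base
      rows[[1L]] <- data.table(chrom = chroms[ci], pos = snp_pos - 1L,
                               ref = x[snp_pos], alt = alt_base, type = "SNP")
    }
    indel_rows <- NULL
    if (length(indel_pos)) {
      ilen <- sample(1:3, length(indel_pos), replace = TRUE)
      is_ins <- runif(length(indel_pos)) < 0.5
      ins_seq <- vapply(ilen, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
      indel_rows <- data.table(
        chrom = chroms[ci], pos = indel_pos - 1L,
        ref = ifelse(is_ins, "-",
                     vapply(seq_along(indel_pos), function(i)
                       paste(x[indel_pos[i]:(indel_pos[i] + ilen[i] - 1L)],
                             collapse = ""), character(1))),
        alt = ifelse(is_ins, ins_seq, "-"),
        type = ifelse(is_ins, "ins", "del"),
        ilen = ilen, is_ins = is_ins)
      ## apply indels right to left so earlier coordinates stay valid
      ord <- order(indel_pos, decreasing = TRUE)
      ychars <- y
      for (i in ord) {
        p <- indel_pos[i]
        if (indel_rows$is_ins[i]) {
          ychars <- c(ychars[seq_len(p)],
                      strsplit(indel_rows$alt[i], "")[[1L]],
                      if (p < length(ychars)) ychars[(p + 1L):length(ychars)])
        } else {
          l <- indel_rows$ilen[i]
          ychars <- c(ychars[seq_len(p - 1L)],
                      if (p + l <= length(ychars))
                        ychars[(p + l):length(ychars)])
        }
      }
      y <- ychars
    }
    ## alternate-coordinate positions: cumulative indel shift before each pos
    tt <- rbindlist(c(rows, list(
      if (!is.null(indel_rows)) indel_rows[, c("chrom", "pos", "ref",
                                               "alt", "type")])),
      use.names = TRUE, fill = TRUE)
    if (nrow(tt)) {
      shift_at <- function(p0) {
        if (is.null(indel_rows) || nrow(indel_rows) == 0L) return(0L)
        before <- indel_rows$pos < p0
        as.integer(sum(ifelse(indel_rows$is_ins[before],
                              indel_rows$ilen[before],
                              -indel_rows$ilen[before])))
      }
      tt[, `:=`(alt_pos = pos + vapply(pos, shift_at, integer(1)))]
      setorder(tt, pos)
      truth[[length(truth) + 1L]] <- tt
    }
    alt[[ci]] <- y
  }
  truth <- if (length(truth)) rbindlist(truth) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), type = character(), alt_pos = integer())
  truth[, in_footprint := NA]
  list(
    reference = Biostrings::DNAStringSet(
      vapply(ref, paste, character(1), collapse = "")),
    alternate = Biostrings::DNAStringSet(
      vapply(alt, paste, character(1), collapse = "")),
    truth = truth[],
    repeats = repeats[, c("chrom", "start", "end")],
    duplications = duplications
  )
}

#' Flag truth variants inside selected-tag footprints
#'
#' @param truth Truth table from [make_parent_genomes()].
#' @param tags Tag table from [extract_tags()] (reference coordinates).
#' @return `truth` with `in_footprint` set by interval intersection.
#' @export
flag_truth_in_footprints <- function(truth, tags) {
  truth <- data.table::copy(as.data.table(truth))
  truth[, in_footprint := positions_in_intervals(chrom, pos, tags)]
  truth[]
}

#' Sample overdispersed per-tag read counts
#'
#' Gamma-mixed Poisson: counts are `Poisson(mu * g)` with
#' `g ~ Gamma(shape, mean 1)`, giving `Var/mean = 1 + mu/shape`.
#'
#' @param n Number of tags.
#' @param mu Mean reads per tag.
#' @param shape Gamma shape parameter.
#' @return Integer vector of counts.
#' @export
sample_tag_counts <- function(n, mu, shape) {
  g <- rgamma(n, shape = shape, rate = shape)
  rpois(n, mu * g)
}

#' Simulate pooled 33-mer tag reads from two parents
#'
#' Digests both parents with the same enzyme, size-selects, extracts terminal
#' tags, and emits reads per tag with Gamma-overdispersed counts. Tags whose
#' footprint overlaps the repeat annotation by at least half its length have
#' their expected coverage multiplied by `repeat_coverage_multiplier`,
#' reproducing repeat-driven pile-up. 5' tags are read in reference
#' orientation, 3' tags from the opposite strand (reverse complement), as a
#' fragment is sequenced inward from either end. Each emitted base is
#' substituted with probability `base_error_rate` (quality dropped to Q10)
#' and replaced by 'N' with probability `n_rate` (Q2); untouched bases carry
#' Q30. Pooling is exactly 50:50.
#'
#' @param reference,alternate Parental genomes ([Biostrings::DNAStringSet]).
#' @param enzyme An [enzyme_spec()].
#' @param size_range Length-2 inclusive size-selection window (bp).
#' @param config A [sim_config()]; supplies coverage, error and seed
#'   parameters.
#' @param repeats Repeat annotation table (reference coordinates), or `NULL`.
#' @return A list:
#'   \describe{
#'     \item{reads}{`data.table` of `id`, `sequence`, `quality`.}
#'     \item{tags}{Per-tag metadata: `parent`, `tag_id`, `chrom`, `start`,
#'       `end`, `side`, `repetitive`, `count`.}
#'   }
#' @export
simulate_tag_reads <- function(reference, alternate, enzyme,
                               size_range = c(70L, 200L), config,
                               repeats = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tag_len <- config$tag_len
  tag_tables <- lapply(
    list(ref = reference, alt = alternate),
    function(g) {
      frags <- digest(g, enzyme, sequences = FALSE)
      sel <- size_select(frags, size_range[1L], size_range[2L])
      extract_tags(sel, tag_len = tag_len, genome = g)
    })
  tags <- rbindlist(tag_tables, idcol = "parent")
  tags[, collapsed := NULL]
  rep_frac <- tag_repeat_fraction(tags, repeats)
  tags[, repetitive := rep_frac >= 0.5]

  set.seed(stage_seed(config$seed, "coverage"))
  g <- rgamma(nrow(tags), shape = config$gamma_shape,
              rate = config$gamma_shape)
  lam <- config$mean_tag_coverage * g *
    ifelse(tags$repetitive, config$repeat_coverage_multiplier, 1)
  tags[, count := rpois(.N, lam)]

  ## emit reads: read-orientation sequence per tag
  read_seq <- tags$sequence
  is3p <- tags$side == "3p"
  read_seq[is3p] <- revcomp_chr(read_seq[is3p])

  idx <- rep(seq_len(nrow(tags)), tags$count)
  reads <- data.table(
    id = paste0(tags$parent[idx], "|", tags$tag_id[idx], "|",
                sequence(tags$count)),
    sequence = read_seq[idx]
  )

  set.seed(stage_seed(config$seed, "errors"))
  n_reads <- nrow(reads)
  q30 <- strrep("?", tag_len)  # Phred+33: '?' = Q30
  reads[, quality := q30]
  if (n_reads > 0L) {
    n_err <- rbinom(n_reads, tag_len, config$base_error_rate)
    n_n <- rbinom(n_reads, tag_len, config$n_rate)
    touched <- which(n_err > 0L | n_n > 0L)
    for (i in touched) {
      s <- strsplit(reads$sequence[i], "")[[1L]]
      q <- rep("?", tag_len)
      if (n_err[i] > 0L) {
        p <- sample.int(tag_len, n_err[i])
        s[p] <- vapply(s[p], function(b) sample(setdiff(BASES, b), 1L),
                       character(1))
        q[p] <- "+"                    # Q10
      }
      if (n_n[i] > 0L) {
        p <- sample.int(tag_len, n_n[i])
        s[p] <- "N"
        q[p] <- "#"                    # Q2
      }
      data.table::set(reads, i, "sequence", paste(s, collapse = ""))
      data.table::set(reads, i, "quality", paste(q, collapse = ""))
    }
  }
  tags[, sequence := NULL]
  list(reads = reads[], tags = tags[])
}

#' Method-of-moments fit of the Gamma-Poisson coverage model
#'
#' For counts `Poisson(mu * g)`, `g ~ Gamma(k, mean 1)`, the marginal moments
#' give `mean = mu` and `Var = mu + mu^2 / k`, so
#' `k_hat = mean^2 / (Var - mean)`. When the sample variance does not exceed
#' the mean (no detectable overdispersion) the shape is reported as `Inf`.
#'
#' @param per_tag_counts Integer vector of per-tag read counts.
#' @return A list with `shape`, `mean`, and `var_mean_ratio`.
#' @export
fit_gamma_overdispersion <- function(per_tag_counts) {
  per_tag_counts <- as.numeric(per_tag_counts)
  if (sum(per_tag_counts >= 1) < 100L) {
    stop("need at least 100 tags with count >= 1 to fit the coverage model")
  }
  m <- mean(per_tag_counts)
  v <- stats::var(per_tag_counts)
  shape <- if (v <= m) Inf else m^2 / (v - m)
  list(shape = shape, mean = m, var_mean_ratio = v / m)
}
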