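---
title: "Reduced-representation SNP discovery: models and design choices"
author: "rrsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-representation SNP discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fine-mapping a QTL needs many markers inside a specific cross, but
re-sequencing a large duplicated plant genome end-to-end to find them is
wasteful. A reduced-representation library (RRL) sequences a reproducible
slice of the genome instead: digest pooled genomic DNA of the two mapping
parents with a blunt-cutting 4-bp restriction enzyme, gel-select fragments of
70–200 bp, and sequence the terminal 33 bp of each fragment end on a
short-read instrument. Every SNP between the parents that falls inside a
sequenced tag is then discoverable by aligning tags to the reference
assembly and looking for consistent mismatches.

`rrsnp` implements this whole workflow in silico: enzyme evaluation by
virtual digestion, a synthetic two-parent study generator, tag alignment,
two-tier SNP filtering, and the survey statistics used to understand
coverage bias and validation rates. Because no public read set accompanies
the study design this package emulates, the generator is a first-class
module: every downstream stage is exercised end-to-end on synthetic genomes
with a known variant truth table.

# In-silico digestion and enzyme evaluation

Digestion scans the forward strand for the IUPAC recognition pattern.
All seven bundled enzymes (Acc II, Hae III, Rsa I, Dpn I, Alu I, CviR I,
CviJ I) have IUPAC-palindromic sites, so forward-strand scanning is exact;
the `enzyme_spec()` constructor *rejects* non-palindromic patterns rather
than silently undercounting. `N` never matches. Methylation sensitivity
(Dpn I) is ignored: counts are sequence-only. Overlapping degenerate-site
occurrences each cut; duplicate cut coordinates are collapsed.

The metric panel (`digest_metrics()`) uses three constants, all arguments
rather than hard-coded values:

* `genome_length` = 1.1e9 bp,
* `snp_rate_bp` = 5,000 (one SNP per 5 kbp between the parents),
* `run_output_bp` = 1.9242e9 (usable bases per sequencing run).

With these, the panel reproduces the published enzyme-comparison table to
its printed precision, e.g.

```{r metrics}
library(rrsnp)
digest_metrics(n_total = 4267589, n_selected = 1367611,
               total_selected_length = 173686597)
#   ... coverage_per_run 11.07858  tag_density_per_mbp 2486.565
#   predicted_snps 18052.47  pct_selected_portion 32.04646
```

Two published columns are *not* reproduced by design. The "% selected
fragments containing repetitive elements" column has no recoverable
denominator; `compute_digest_report()` instead reports an explicitly defined
pair: `n_repetitive_selected` (a selected fragment is repetitive when either
terminal 33-mer overlaps repeat annotation by ≥ 50 % of its bases,
threshold configurable) and `pct_repetitive_selected` = 100 ×
`n_repetitive_selected / n_selected`. Likewise the implied per-run yield
(1.9242 Gb) differs from the reported two-flow-cell yield (1.47 Gb); the
value is a parameter and the discrepancy is left unreconciled.

Size-selection bounds are inclusive on both ends ("between 70 and 200 bp"
is ambiguous; inclusive is chosen and configurable). Coordinates are
0-based half-open internally and 1-based in all user-facing files.

# The synthetic study generator

`make_parent_genomes()` builds, under one root seed:

* a random background genome (default 1 Mbp over 2 chromosomes);
* three repeat families (monomers of 150/400/800 bp) whose copies are
  placed uniformly and individually diverged by 5 % substitutions,
  covering ≈ 59 % of the genome — the repeat content of the genome the
  design targets. Monomers are GC-balanced by construction because the
  coverage model deliberately has **no** GC effect; unbalanced monomers
  would smuggle a spurious GC–coverage correlation in through repeat
  pile-up;
* segmental duplications ("paralog traps"): 5 segments of 2 kbp copied to
  a second locus at 1 % divergence, present in the reference and hence in
  both parents, and deliberately *absent* from the repeat annotation —
  they are what produces paralog-driven false calls at the lenient tier;
* an alternate parent differing by SNPs at 1/5,000 bp and 1–3 bp indels at
  2 × 10⁻⁵/bp (sparse, as expected between two cultivars; the indels exist
  to exercise the indel-proximity filter). Colliding edits are skipped and
  logged.

`simulate_tag_reads()` digests both parents, size-selects, and emits both
33-bp terminal tags per selected fragment: the 5' tag in reference
orientation and the 3' tag as its reverse complement (a fragment is read
inward from either end). Per-tag read counts follow a Gamma-mixed Poisson:
`count ~ Poisson(mu * g)`, `g ~ Gamma(shape = k, mean = 1)`, so
`Var/mean = 1 + mu/k`; defaults `mu = 20`, `k = 1` give the strong
overdispersion seen in real tag libraries. Tags whose footprint is ≥ 50 %
repeat-annotated have their rate multiplied by 5, reproducing repeat-driven
pile-up (high-coverage tags end up overwhelmingly repetitive, low-coverage
tags much less so). Pooling is exactly 50:50.

The error model is deliberately simple and fully declared: each emitted
base substitutes with probability 0.001 (quality dropped to Q10), becomes
`N` with probability 0.0009 (Q2), and otherwise carries Q30. Real
quality strings are heterogeneous and position-dependent; this model keeps
the caller honest (errors are low-quality, real alleles are not) without
claiming to emulate a particular instrument. Consequences for
interpretation: passing tests show the ladder's *logic* is right under a
faithful error-labelling, not that the package's thresholds are calibrated
for any specific sequencer.

Reproducibility: every stage derives a named sub-seed from the root seed,
so adding or reordering a stage never shifts another stage's draws, and a
fixed configuration yields byte-identical FASTA/FASTQ/BED/VCF artifacts.

# Alignment and the mapping-quality proxy

Tags are aligned ungapped with at most 2 mismatches by seed-and-verify:
the 33-mer is split into three non-overlapping 11-mer seeds; by pigeonhole
any qualifying placement leaves one seed exact, so exact-seed lookup plus
Hamming verification is complete. Reads containing `N` are discarded before
alignment (the published rule), not soft-masked. Reverse-strand hits are
reported in forward coordinates with a strand flag. Ties at the minimum
mismatch count are all retained in `n_best_hits`; the reported placement is
the lowest (chromosome, coordinate), forward strand first, for determinism.

A full MAQ-style quality model is out of scope; a declared proxy stands in:

* MQ 40 — unique best hit, no other placement within the tolerance;
* MQ 25 — unique best hit, second-best at strictly more mismatches;
* MQ 0 — tied best placements.

The stringent filter consumes only the threshold "MQ of at least 40" and
relative confidence, which the proxy preserves. The published rule says
"higher than 40" while 40 is also the scale maximum; read literally it
would discard everything, so it is interpreted as ≥ 40 (configurable).

# Calling and the two filter ladders

`build_pileup()` gives every covered reference base a column of per-allele
read counts and summed base qualities; ambiguous (MQ 0) alignments
contribute to depth — that is what makes repeat pile-up visible — but are
separable via `mq0_depth`.

**Consensus quality.** The confidence that the alt evidence is not
base-calling error is `Q = min(40, round(-10 log10 p))` with
`p = P(Binomial(depth, e) >= alt_count)` and `e = 10^(-Q̄alt/10)`, where
`Q̄alt` is the mean quality *of the alt-supporting bases*. Using the
alt-specific quality (rather than the whole column's mean) is the point:
a single Q10 error read in a deep column gets `e = 0.1`, `p ≈ 1`, `Q = 0`,
while a real allele supported by Q30 bases scores highly. Candidates
additionally require `Q >= 1` to enter the list at all — without that gate
every singleton sequencing error at a covered column becomes a "candidate"
and poisons the 10-bp window rule below; a MAQ-style caller likewise only
reports sites where the consensus departs from the reference.

**Lenient tier** (in order): read depth ≥ 3; position not inside a repeat
interval (point-in-interval — the rule addresses SNPs *located in*
repetitive regions, not tag overlap); then a window purge: if any 10-bp
reference window `[p, p+10)` contains ≥ 3 surviving candidates, *all*
candidates in that window are removed. Positions 100 and 109 co-occupy a
window; 100 and 110 do not.

**Stringent tier**, applied on top of the lenient tier (the nesting is a
design choice; the two published counts are consistent with it): distance
to the nearest indel > 3 bp (boundary inclusive: |SNP − indel| ≤ 3
discards); depth ≥ 10; at least one covering read with MQ ≥ 40; consensus
quality ≥ 10; window rule re-applied. The published stringent rule 3 mixes
a mapping-quality condition and a window condition in one sentence; both
are implemented as separate conjuncts and both appear in the audit file.

Depth, not alt-supporting count, is what both read-count thresholds test:
MAQ-style SNP rows carry read depth, and "supported by at least ten short
sequence reads" reads most naturally as depth. Both thresholds are
arguments.

The indel track comes from the simulation truth in synthetic runs or a
user-supplied BED otherwise; the package does no gapped alignment and
calls no indels (33-bp reads make that impractical), which is why the
stringent ladder defends against indel-adjacent misalignment instead.

**Cross-assembly exclusion.** The supporting tag of each candidate is
re-aligned to a second assembly (which may equal the first): candidates
whose tag has more than one best position are dropped (multi-position
rule), as are candidates whose tag cannot be placed on the repeat-masked
second assembly at all.

**Known non-monotonicity.** Because the window purge removes *sets* of
candidates, deleting reads or raising thresholds can resurrect a
previously-purged neighbour; call sets are therefore not globally monotone
in the thresholds. This is a property of the published rule itself, not of
the implementation; the monotonicity that does hold (nested depth
thresholds with the purge disabled) is what the tests assert.

# Recovery scoring on synthetic studies

`score_recovery()` reports recall and precision of a call set against the
spiked truth inside a *callable region*:

* unique selected-tag footprints — footprints of reference-parent tags
  that align back uniquely (MQ 40): outside them the stringent MQ rule
  forbids calls categorically;
* minus repeat-annotated positions — the lenient repeat rule forbids
  calls there too;
* recall denominator restricted to truth SNPs with ≥ 1 sequenced read of
  the alternate-parent tag carrying them — a variant with zero alt reads
  says nothing about any caller.

Under the default study (1 Mbp, 1 SNP/5,000 bp, `mu = 20`, `k = 1`), a SNP
site is covered by one tag from each parent, so its depth is a sum of two
independent Gamma(1)-mixed Poissons with mean 40. The probability that a
covered site still fails the depth-10 rule is
`P(depth < 10 | covered) ≈ 0.079`, putting the *expected* stringent recall
near 0.92 — but a 1-Mbp genome at this SNP rate yields only ~15 truth SNPs
inside callable footprints, so the observed recall moves in steps of
~1/15 and fluctuates considerably between seeds. The bundled demo seed is
fixed, and the test suite reports exactly what that realisation produces;
precision in callable regions is essentially 1 because low-quality error
evidence is absorbed by the consensus-quality gate and paralog pile-up is
absorbed by the MQ rule. Lenient-tier calls inside the (unannotated)
duplications are counted separately in the run summary — they are the
residual "paralogous SNP" error mode that stringency exists to remove.

# Problem sizes used by the tests

The default test run uses a 1-Mbp two-chromosome study (the bundled demo
configuration, seed 101) for the end-to-end, enrichment, determinism and
recovery checks; a 300-kbp error-free single-chromosome study for the
calling-logic checks; 20-kbp to 100-kbp random sequences for the digestion
and alignment oracle comparisons (20 × 100 kbp × 7 enzymes for digestion;
1,000 mutated tags against exhaustive scanning for the aligner); and
10,000 tags for overdispersion parameter recovery. These sizes keep the
whole suite under a few minutes while leaving every property with enough
events to be informative.

# Survey statistics

"Sliding windows" are implemented as non-overlapping tiles (step = width,
configurable) of 10 kbp; reads are assigned to the window containing their
leftmost mapped coordinate, weighted by duplicate count, so window counts
conserve the total. GC fractions exclude `N` from the denominator.
Correlations use the standard product-moment formula (`stats::cor` behind
a zero-variance guard, cross-checked in the tests against direct
summation). Percentages round half-up at the caller-chosen precision,
because the emulated report mixes 0- and 1-decimal rounding.

# Limitations

* Ungapped alignment only; indels are consumed as an exclusion track,
  never called.
* The quality/error model is a two-level declaration, not an instrument
  profile; thresholds involving base quality should be recalibrated for
  real data.
* The MQ proxy has three levels; anything needing graded mapping
  confidence between 0 and 40 will not find it here.
* The generator's repeat families are uniformly placed mutated monomers;
  real repeat landscapes are clustered and nested, so repeat-driven
  coverage artefacts in real data can be worse than simulated.
* Biallelic sites only (a pooled two-inbred design implies it); pool
  allele frequencies are not estimated — read depth here is far below
  what that would need.
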