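---
title: "Identifying miRNA mutation and editing sites: models and methods"
author: "miredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying miRNA mutation and editing sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredit)
```

## The problem

Mature miRNAs frequently differ from their genomic template: A-to-I editing
by ADAR deaminases (read as A→G by sequencers), C-to-U editing by APOBEC
enzymes, non-templated 3' additions (adenylation stabilizes, uridylation
destabilizes the miRNA), and 5' additions that shift the seed region and
retarget the miRNA. `miredit` identifies such mutation/editing (M/E) sites
from small RNA sequencing profiles, quantifies per-sample editing levels,
filters them against sequencing error and SNPs, and compares editing levels
between cohorts (for example disease versus control). Every stage is
exercised end to end on synthetic reads with known ground truth, generated
by the package's own simulator.

## Pipeline model

### Read qualification

A read passes quality screening iff each of its first
`min(prefix_length, read length)` bases (default 25) has Phred quality at or
above `quality_threshold` (default 30, Phred+33 encoding, no
autodetection). The 3' adapter is located by the leftmost exact match of
its first `min_overlap = 6` bases and the read truncated there; trimmed
reads shorter than 18 nt are discarded. Reads with no detectable adapter
are rejected by default — an untrimmed read would carry adapter bases into
alignment as spurious mismatches — but `qc_params(require_adapter = FALSE)`
passes them through, since the correct treatment of adapter-free reads is
genuinely open. Surviving reads are collapsed to unique sequences with
multiplicities; all later stages operate on collapsed reads.

### Alignment model

Collapsed reads are aligned to the hairpin precursors ungapped, tolerating
at most one internal mismatch and a non-templated 3' tail of at most 5 nt,
with a body (the templated part) of at least 16 nt so that an 18-nt read
may carry a 2-nt tail. The tail is defined by the maximal-templated-suffix
rule: the shortest suffix such that the remaining body holds within the
mismatch budget. A consequence worth knowing: a single mismatching terminal
base is absorbed as the internal mismatch when the budget is free, and
becomes a tail base otherwise. The downstream site representation is
identical either way, because classification depends only on the site's
position relative to the mature 3' terminus. Indels are not modeled.

This single alignment model replaces the two-tool arrangement (a BLASTN
pass over precursors followed by Bowtie `-a -best -v 1` over the genome)
that pipelines of this kind traditionally use: the downstream taxonomy
consumes exactly single-nucleotide variants at precursor positions plus a
short tail, which the unified model produces without external binaries and
without an unspecified reconciliation rule between two aligners.

Precursor-mapped reads are then aligned to the genome (both strands, no
gaps, at most one mismatch), keeping every placement that achieves the
read's minimum mismatch count ("best" semantics). String matching uses
Biostrings; the test suite checks it against an exhaustive
offset-by-offset scan.

### Cross-mapping correction

A read mapping to several genomic loci is allocated fractionally. Weights
start uniform over the read's loci. Each sweep computes every locus's
expression as the count-weighted sum of weights of all placements whose
intervals intersect it, removes the read's own contribution
(leave-self-out), sets the read's weight at each locus proportional to the
remaining support, and renormalizes. Iteration stops when the largest
weight change falls below `tol = 1e-6` or after `max_iter = 100` sweeps.
A read whose loci all have zero external support keeps its uniform
weights. Weights sum to one per read after every sweep by construction,
and the diagnostics attached to the result record the convergence trace.

Precursor placements then receive the weight of the read's genomic
placements inside the precursor locus. Two special cases are deliberate:

* a read that maps to the genome but never inside the precursor locus gets
  weight 0 and is flagged a cross-mapping *orphan* — its apparent editing
  is better explained by another locus;
* a read with no genomic placement at all keeps weight 1. These are
  typically tailed reads whose non-templated bases exceed the genomic
  mismatch budget; they cannot cross-map, and treating them as orphans
  would misclassify every tailing event as Pseudo.

### Site calling

For every precursor position the pileup tallies weighted and raw support
per observed nucleotide; a placement covers its body and any tail bases
lying at precursor coordinates. Each observed non-reference nucleotide at
a covered position is a candidate site.

The editing level is the edited weight divided by the total weighted
coverage at the site's *anchor*: the site position itself for central
sites, the governing mature's 3' terminus for sites past it, and the
mature's 5' start for sites before it. The anchor matters for addition
sites: only edited reads physically reach a tail position, so coverage at
the position itself would force every tail site to a 100% level; the
anchor denominator instead expresses "the fraction of this miRNA's reads
that carry the addition", which is the quantity the field reports and the
only one for which the 100%-level SNP criterion is informative.

Significance testing is a one-sided binomial test of the raw edited count
against the raw anchor coverage with per-base error rate
$e = 10^{-Q/10}$ implied by the quality threshold ($e = 0.001$ at Q30) —
the natural reading of a score-threshold criterion, since the test itself
is otherwise unspecified in this setting. Raw integer counts feed the
test (fractional trials are ill-defined for a binomial); cross-mapping
weights feed the editing level. P-values are Benjamini–Hochberg corrected
within each sample, the family being all candidate sites of that sample —
the per-sample reading is chosen because the cross-sample retention rule
is applied afterwards, on the per-sample outcomes. A site is significant
iff its level is at least `min_level = 0.05`, its raw edited support at
least `min_reads = 10` (raw rather than weight-corrected reads — the
stricter reading), and its corrected p-value below `alpha = 0.05`.

### Classification

Each candidate receives exactly one of nine categories. The governing
mature miRNA is the one whose extended region (mature ± `max_tail`)
contains the position; with two candidates the nearer terminus wins and
ties go to the 5p arm. Sites past the mature 3' end are 3'-A, 3'-U or
3'-Other by their added nucleotide; sites before the 5' start are
5'-editing; central sites are A-to-I (A→g), C-to-U (C→u) or Other. A site
whose alt-supporting reads are mostly cross-mapping orphans (fraction
above `pseudo_threshold = 0.5`; the threshold is a package decision, as
the Pseudo category has no published definition) is Pseudo. SNP status is
decided at the cohort stage: a site becomes SNP iff its genomic position
matches a catalog entry, both alleles match on the genome strand
(minus-strand sites are complemented before comparison), and its editing
level reaches 100% in at least one sample.

### Cohort aggregation and retention

Per-sample tables are merged by site identity. A cell is 0 when the sample
covered the anchor but showed no edited reads, and missing when the anchor
itself was uncovered; the distinction is kept through differential testing
(pairwise deletion) rather than imputed. A site is retained iff it is
significant in at least `min_sample_threshold(0.2, n)` of the combined
cases-plus-controls cohort, where the threshold is the nearest integer
with ties rounded up and a floor of one — the rule that reproduces all
four published cohort thresholds (10 of 52, 5 of 25, 11 of 56, 14 of 70).

### Differential editing and multivariate analysis

Editing levels are compared between groups per site with a two-sided
Mann–Whitney U test: exact by enumeration when the combined sample size is
at most 12 without ties, otherwise the normal approximation with tie and
continuity corrections. P-values are BH-corrected per comparison (each
cohort-versus-control comparison forms its own family). Quantile
normalization is the standard rank-average transform
(`limma::normalizeQuantiles`, ties averaged, missing cells excluded and
restored). PCA is column-mean-centered unscaled covariance PCA of samples,
with missing cells imputed to the site's cohort mean and the sign
convention that each component's largest-magnitude loading is positive.
Clustering uses one minus the Pearson correlation of the normalized values
plus one as the sample distance — the +1 offset is retained for fidelity
to the original procedure although correlation is shift-invariant, so it
is a documented no-op — with Ward-D2 agglomeration; constant samples have
undefined correlation and get distance 1.

## The simulator

`sim_config()`/`generate_reference()`/`simulate_sample()` emulate the
study's inputs: hairpins of 70–100 nt with annotated 20–23 nt mature arms
embedded in a random background genome on either strand; injected central
substitutions, C-biased 5' additions (70% C by default) and A/U-biased 3'
tails (60% A / 30% U / 10% other, geometric lengths with p = 0.5) —
proportions chosen to mirror the qualitative dominance of 3'-A and 3'-U
and the 5' C preference seen in real profiles, not any exact published
fractions; germline variants at level 1.0 with matching SNP-catalog
entries; per-base sequencing errors (default 0.001, the Q30-implied
rate); constant Q38 qualities; 3' adapters; optional templated 3' isomiR
extensions; and paralogous loci, either as exact extra genomic copies or
as annotated second precursors sharing the 5p mature arm with a divergent
3p arm and their own expression level, to exercise cross-mapping. Each
sample draws from an RNG stream derived from (master seed, sample index),
so any sample is reproducible in isolation, and identical configuration
plus seed yields byte-identical reference files.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic expression distributions
across a full miRNome, ligation and GC biases, position-dependent error
profiles, quality-score variation, indels, and co-occurring edits on the
same read (several simultaneous substitutions exceed the one-mismatch
alignment budget, so the simulator's study conditions place at most one
substantial editing site per mature arm, matching the sparse-editing
regime the identification model assumes). When several chained 3'
addition events are configured on one arm, a read carries a later tail
base only if it carries all earlier ones, so realized chained proportions
are conditional; ground truth records realized counts.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout, matching miRBase GFF3.
* Precursors annotated at several loci keep the first (with a warning);
  precursors without mature annotations are dropped.
* `N` is allowed in the genome and precursor loops but rejected inside
  mature regions, where sites would be uncallable; `N` pileup
  observations are never candidate sites.
* Zero-coverage positions are absent from the pileup; a site whose anchor
  has zero weighted coverage gets a missing level and is never significant.
* The cross-mapping fallback (all-zero external support) keeps current
  weights rather than dividing by zero; expressions are clamped at zero
  against floating-point drift.
* Mann–Whitney on two identical constant groups returns p = 1 by
  definition rather than NaN from a zero-variance approximation.
* `n = 0` binomial tests return NA and the site is skipped.
* Catalog TSVs are read with all-character columns first — a lone `T`
  allele would otherwise be type-converted to logical.

## Problem sizes in the shipped tests

The suite validates level recovery over 100 seeded pipeline replicates at
1000× coverage (θ ∈ {0.1, 0.3, 0.5}, one site per precursor), error
control over 50 zero-editing samples at error rate 0.001, differential
recovery over 20 seeded two-group simulations (20 vs 20 samples, Δθ = 0.2
at 5 of 55 sites, coverage 500×), oracle equivalence on 200 reads against
a 10-kb genome, and the SNP/Pseudo/cross-mapping constructions described
above. These sizes are the package's chosen validation conditions: large
enough that binomial noise is well inside the asserted tolerances, small
enough to run routinely.

## Known limitations

* The cross-mapping update is expression-driven only; it does not add
  sequence-similarity terms, and published descriptions of the original
  algorithm leave those details open.
* The aligner is specialized to the site taxonomy (ungapped, one internal
  mismatch, short 3' tail); it is not a general-purpose read mapper, and
  insertion/deletion events are out of scope.
* Editing levels at multi-allelic positions yield one site per alternative
  nucleotide sharing the same denominator.
* With paralogs, raw read counts (used by the binomial test) are counted
  at every placement, while weights are corrected; heavily cross-mapped
  regions therefore rely on the orphan/Pseudo mechanism rather than on
  count splitting.
* PAR-CLIP-based target prediction, GO/KEGG enrichment and count-based
  expression testing (edgeR-style) are outside the package's scope.
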