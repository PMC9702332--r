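# miredit

Identification and cohort analysis of miRNA mutation/editing (M/E) sites
from small RNA sequencing data.

Mature miRNAs often differ from their genomic template: A-to-I editing by
ADAR enzymes (sequenced as A→G), C-to-U editing by APOBEC enzymes,
non-templated 3' adenylation/uridylation, and 5' additions that shift the
seed region and retarget the miRNA. `miredit` is for researchers who want
to call such sites from FASTQ profiles, quantify per-sample editing
levels, separate them from sequencing error, cross-mapping artifacts and
SNPs, and compare editing between cohorts (e.g. leukemia subtypes versus
normal controls) — with every stage testable end to end on simulated reads
with known ground truth.

## The method in brief

Reads passing quality screening (first 25 nt at Phred ≥ 30, 3' adapter
removed, length ≥ 18 nt) are collapsed and aligned ungapped to pre-miRNA
hairpins, allowing ≤ 1 internal mismatch and a non-templated 3' tail of
≤ 5 nt. Precursor-mapped reads are aligned to the genome (all best loci,
≤ 1 mismatch) and multi-mapped reads are fractionally allocated by the
cross-mapping correction: weights per locus proportional to locus
expression with the read's own contribution removed, iterated to a fixed
point, so that Σ<sub>loci</sub> w = 1 per read.

A candidate site at precursor position *p* with edited weight *w*, anchor
coverage weight *W*, raw edited count *k* and raw anchor coverage *n* has

* editing level = *w*/*W*,
* one-sided binomial p-value P(X ≥ k), X ~ Binomial(*n*, *e*), with
  *e* = 10^(−Q/10) = 0.001 at the Q30 score threshold,

and is significant iff level ≥ 5%, *k* ≥ 10 and the per-sample
Benjamini–Hochberg corrected p < 0.05. Sites are classified into nine
categories (A-to-I, C-to-U, 3'-A, 3'-U, 3'-Other, 5'-editing, Other, SNP,
Pseudo), named `<precursor>_<pos>_<REF>_<alt>` (e.g.
`hsa-mir-376a-1_9_A_g`), and kept per cohort when significant in at least
20% of combined case + control samples. Cohort comparisons use two-sided
Mann–Whitney U tests (exact for n ≤ 12 without ties) with BH correction;
multivariate views use quantile normalization, covariance PCA and Ward-D2
clustering on 1 − Pearson correlation distances. The bundled simulator
generates hairpins, genomes with paralogous loci, reads with injected
events, error models and adapters, plus machine-readable truth tables.

See `vignettes/miredit-methods.Rmd` for the full model description,
parameter defaults and design decisions.

## Worked example

Simulate a two-group cohort (6 leukemia-like, 6 control samples; three
hairpins) carrying a differential A-to-I site, a 3'-A tailing site, a 5'
C-addition and a germline variant, then run the full pipeline:

```r
library(miredit)

events <- data.frame(
  precursor = c(1, 1, 2, 3),
  type      = c("central", "three_prime", "five_prime", "central"),
  arm       = c("5p", "5p", "5p", "5p"),
  offset    = c(9, 1, 1, 6),
  ref       = c("A", NA, "G", "C"),
  alt       = c("G", "A", "C", "U"),
  theta_leukemia = c(0.40, 0.35, 0.25, 1.0),
  theta_control  = c(0.10, 0.30, 0.25, 1.0),
  germline  = c(FALSE, FALSE, FALSE, TRUE))

cfg    <- sim_config(n_precursors = 3, depth = 400,
                     groups = c(leukemia = 6, control = 6), events = events)
ref    <- generate_reference(cfg, seed = 101)
cohort <- simulate_cohort(ref, master_seed = 2024)

res <- run_cohort(cohort, ref)   # per-sample calls -> merge -> retain -> SNP
res$retained$sites[, c("name", "category", "n_significant", "max_level")]
#>               name   category n_significant max_level
#> 1 sim-mir-1_12_A_g     A-to-I            12 0.4229391
#> 2 sim-mir-1_26_G_a       3'-A            12 0.3754513
#> 3  sim-mir-2_4_G_c 5'-editing            12 0.2831541
#> 4 sim-mir-3_11_C_u        SNP            12 1.0000000

labels <- factor(attr(cohort, "groups"), levels = c("leukemia", "control"))
dt <- differential_table(res$retained, labels)
dt[, c("name", "mean_a", "mean_b", "U", "p_bh", "direction", "significant")]
#>               name mean_a mean_b  U  p_bh direction significant
#> 1 sim-mir-1_12_A_g  0.401 0.0907 36 0.010        up        TRUE
#> 2 sim-mir-1_26_G_a  0.354 0.3102 36 0.010        up        TRUE
#> 3  sim-mir-2_4_G_c  0.250 0.2515 17 0.936      down       FALSE
#> 4 sim-mir-3_11_C_u  1.000 0.9994 21 0.540        up       FALSE
```

All four injected sites are recovered with their intended categories and
levels close to the injected proportions; the germline variant (level 100%
everywhere, present in the simulated SNP catalog) is reclassified as SNP;
the two sites injected with higher levels in the leukemia group — the
A-to-I site (0.40 vs 0.10) and, more subtly, the 3'-A site (0.35 vs
0.30) — are the ones flagged as differentially edited, both in the "up"
direction, while the non-differential 5' site and the SNP are not.

Real data enter through the same surfaces: `load_premirnas()` (miRBase
FASTA + GFF3), `read_fastq()`/`run_sample()` per profile, `load_catalog()`
for SNP/known-site TSVs, then `merge_samples()`, `retention_filter()`,
`snp_reclassify()` and the `diffstats` functions.

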