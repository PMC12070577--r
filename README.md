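# polyatails

Read-level poly(A) tail and transcript-usage analysis for Oxford Nanopore
direct RNA sequencing, aimed at two-condition cohort comparisons — the
motivating design is whole blood from 12 sepsis patients, 6 with confirmed
bacterial and 6 with confirmed viral infection. Direct RNA sequencing reads
native mRNA molecules, so each read carries an estimate of its poly(A) tail
length (an integer auxiliary tag on the BAM record) and full isoform
structure; this package turns those observables into candidate biomarkers.

## What it computes

* **Poly(A) profiling** — per-gene tail summaries, mitochondrial vs nuclear
  stratification (mito tails cluster tightly near 45 nt; nuclear tails are
  broad with a long right tail), and the gene ranking by median tail length.
* **Differential polyadenylation (DP)** — per gene, a linear mixed model on
  log2 tail length,

  `log2(polya_length) ~ condition + (1 | batch)`

  fitted by REML with Satterthwaite degrees of freedom; the condition
  coefficient is the log2 fold-change (viral − bacterial). Genes are called
  differentially polyadenylated at BH-adjusted p < 0.05 **and**
  |log2FC| ≥ 0.5, and calls are stress-tested by a 100× within-sample
  bootstrap (`robust_fraction`).
* **Pre-ranked GSEA** — weighted Kolmogorov–Smirnov running-sum enrichment
  scores on the tail-length ranking, gene-label permutation null, NES and
  same-sign pooled FDR q-values, leading-edge extraction.
* **Quantification concordance** — TPM/CPM computation, per-sample and
  per-feature Pearson correlation with expression-filter sweeps, Fisher-z
  comparison of correlations, per-sample Jensen–Shannon divergence, and
  length/GC bias regressions.
* **Differential transcript usage (DTU)** — DRIMSeq-style expression
  filtering (12/4/10/10), a Dirichlet-multinomial likelihood-ratio test with
  common precision profiled under the null, per-transcript tests, and
  stage-wise (screen genes, confirm transcripts) error control.
* **Synthetic cohort generator** — truth-known read-level datasets, paired
  two-platform count matrices, and Dirichlet-multinomial isoform counts,
  calibrated to the study's headline summaries (mean per-gene median tail
  ~83 nt, ~0.2% of tails > 350 nt, mito regime at 45 nt).

All user-facing functions take and return tibbles and chain with the pipe;
fitted results have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
displays.

## Worked example

Simulate a 12-sample cohort (300 nuclear genes, 13 mitochondrial, ~200
reads per gene) with two injected differentially polyadenylated genes, then
profile and test:

```r
library(polyatails)

cfg <- sim_config(
  n_genes = 300, n_mito_genes = 13, reads_per_gene_mean = 200,
  dp_genes = tibble::tibble(gene_id = c("GENE0001", "GENE0002"),
                            delta_log2 = c(1, -0.8)),
  seed = 42
)
sim <- simulate_polya_reads(cfg)

stratify_compartment(sim$reads, sim$gene_models)
#> # A tibble: 2 × 7
#>   compartment       n  mode median frac_gt_70 frac_gt_350 empty
#> 1 mitochondrial  2628    46   44.9   0.000761     0       FALSE
#> 2 nuclear       60223    55   76.7   0.573        0.00213 FALSE

dp <- dp_test(sim$reads)
glance(dp)
#> # A tibble: 1 × 7
#>   n_genes n_dpg  n_up n_down n_robust alpha lfc_threshold
#> 1     313     2     1      1        0  0.05           0.5

head(dplyr::arrange(tidy(dp), p_adj), 3)[, c("gene_id","log2fc","p_adj","is_dpg")]
#>   gene_id  log2fc    p_adj is_dpg
#> 1 GENE0063  0.372 0.000250 FALSE
#> 2 GENE0001  1.02  0.00247  TRUE
#> 3 GENE0002 -0.856 0.00253  TRUE
```

The mitochondrial mode lands at ~45 nt and both injected genes are
recovered with the right sign and magnitude. `GENE0063` shows why the dual
cutoff exists: a tiny p-value with |log2FC| = 0.37 stays uncalled. The
bootstrap confirms the two calls are robust:

```r
bootstrap_robustness(sim$reads, dp, n_boot = 100, seed = 42)
#>   gene_id  robust_fraction is_robust n_replicates_used
#> 1 GENE0001               1 TRUE                    100
#> 2 GENE0002               1 TRUE                    100
```

`run_pipeline(run_config(sim = cfg, seed = 42))` chains simulation,
profiling, DP + bootstrap, GSEA, concordance and DTU, writes one TSV per
result plus a manifest with MD5 checksums, and reproduces every file byte
for byte given the same seed.

Real data enter through `read_polya_bam()` (poly(A) tag, default `pt`),
`read_polya_table()` (the three-column extraction summary),
`read_annotation()` (GTF + optional FASTA for GC), `read_abundance()`
(quantifier TSVs), `read_gmt()` (gene sets) and `read_sample_metadata()`
(sample → batch/condition sidecar).

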