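---
title: "Models and methods behind polyatails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyatails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Oxford Nanopore direct RNA sequencing reads native mRNA molecules end to
end, which makes two quantities observable that short-read cDNA sequencing
cannot deliver: the per-read poly(A) tail length (estimated by the
basecaller and stored as an integer auxiliary tag on each BAM record) and
full-length isoform structure. `polyatails` implements the read-level
statistics needed to turn those observables into candidate disease
biomarkers in a small two-condition cohort — the motivating design is
whole-blood RNA from 12 patients, 6 with confirmed bacterial and 6 with
confirmed viral infection, each sample prepared as its own library batch:

* per-gene and per-compartment poly(A) profiles (mitochondrial transcripts
  carry short, tightly distributed tails around ~45 nt; nuclear transcripts
  a broad distribution with most mass between roughly 50 and 150 nt);
* differential polyadenylation (DP) between conditions, via a per-gene
  linear mixed model on log2 tail length;
* pre-ranked gene-set enrichment on the gene ranking by median tail length;
* concordance between two quantifications of the same samples (long-read
  vs short-read pipelines);
* differential transcript usage (DTU) via a Dirichlet-multinomial
  likelihood-ratio test with stage-wise error control.

Every stage is exercised end to end against a truth-known synthetic data
generator, so the whole pipeline is testable without any sequencing data.

## The synthetic cohort

`sim_config()` fixes the study conditions. Read-level nuclear tails follow

$$\log_2 T_{gri} = \mu_g + \delta_g\,[\text{viral}] + b_{g,\,\mathrm{batch}(i)} + \varepsilon_{gri},$$

with gene baselines $\mu_g \sim N(m, s^2)$ on the log2 scale, per-gene
batch intercepts $b \sim N(0, \sigma_b^2)$ and read noise
$\varepsilon \sim N(0, \sigma_e^2)$. Defaults: $s = 0.55$,
$m = \log_2 83 - s^2 \ln 2 / 2$ (so the expected per-gene median tail is
83 nt, with typical medians spanning roughly 30–160 nt), $\sigma_b = 0.2$,
$\sigma_e = 0.5$. Mitochondrial tails are truncated-normal (centre 45 nt,
sd 8 nt, lower bound 10 nt) with no condition or batch effect, matching
the narrow symmetric mitochondrial regime. Under these defaults about
0.2% of nuclear tails exceed 350 nt, a realistic long-tail fraction for
blood mRNA.

Three deliberate design choices:

* **Batch intercepts are drawn per gene and batch**, not once per batch.
  A shared batch draw would correlate all genes' tests and make a single
  dataset's false-positive fraction wildly variable; per-gene intercepts
  realise exactly the model the per-gene LMM assumes, so calibration is
  testable on one simulated cohort. Each sample is its own batch by
  default (per-patient libraries); any coarser grouping can be supplied.
* **The read-level distribution is lognormal given the gene.** A
  consequence worth knowing: with gene-level spread $s = 0.55$ the
  *density peak* of the pooled nuclear distribution sits near
  $\exp(m\ln 2 - \sigma_{\ln}^2) \approx 60$ nt, well below the 83 nt mean
  of medians — the mode of any lognormal lies below its median. A narrow
  read-level peak near 80 nt and a median span of 26–147 nt cannot both
  hold under one lognormal family; the generator is calibrated to the
  median summary, which is the quantity the downstream ranking and DP
  model consume. Tests of the histogram mode therefore check against the
  model-derived analytic peak, not against 80.
* **Tails below 1 nt are clamped**: the basecaller emits non-negative
  estimates where 0 means "not estimated", and ingestion treats values
  below 1 nt as missing so the log2 response is always defined.

Paired platform counts are bivariate-lognormal per gene with a
configurable cross-platform correlation of the log expected abundances
(default 0.9), optional length and GC biases added to platform A only, and
Poisson sampling around the exponentiated means. Isoform counts are
Dirichlet-multinomial around per-condition proportion vectors with
precision `dm_precision` (default 50) and negative-binomial totals
(default mean 300).

What the generator does **not** emulate: basecalling error and tail
mis-estimation, sequence content, transcript-length-dependent tail
effects, correlated expression between genes, library-size imbalance, and
condition-correlated batch structure. Passing tests demonstrate that the
statistics are correct and calibrated under their assumed models — not
that those models capture every pathology of real cohorts.

## Differential polyadenylation

For each gene with at least `min_reads` usable reads per condition
(default 10) the model

`log2(polya_length) ~ condition + (1 | batch)`

is fitted by REML (lmerTest); the condition coefficient *is* the log2
fold-change (viral − bacterial, positive = longer tails in viral), tested
with Satterthwaite degrees of freedom. When a gene has a single batch, or
the batch-variance estimate hits the zero boundary (singular fit), the
model falls back to ordinary least squares with residual degrees of
freedom — for a two-level factor this is algebraically the pooled-variance
two-sample t-test, and the fit is flagged `method = "ols"`. P-values are
BH-adjusted across fitted genes and a gene is called differentially
polyadenylated when `p_adj < 0.05` and `|log2FC| >= 0.5` jointly.

The log2 response (the paper trail says only "log-transformed") makes the
coefficient directly comparable to the 0.5 cutoff; `min_reads = 10` per
condition is the package's eligibility rule, since none is stated
upstream.

Robustness of DPG calls is assessed by a 100-replicate bootstrap: reads
are resampled with replacement *within each (gene, sample) stratum* —
preserving per-sample depth and the batch/condition design — all
candidates are refitted, and p-values are BH-adjusted across candidates
within each replicate. `robust_fraction` is the fraction of replicates
with `p_adj < 0.05`; a candidate is robust at 0.95 (exposed as
`robust_quantile`). Pooled resampling (`stratify = FALSE`) is available
because the upstream description ("reads assigned to the gene were
resampled") is ambiguous; stratified is the default as it keeps the
design intact.

## Pre-ranked GSEA on tail lengths

Genes are ranked by median tail, longest to shortest, ties broken by gene
id so the ranking is reproducible. The enrichment score is the classic
weighted Kolmogorov–Smirnov running sum (weight exponent 1 by default;
0 gives the unweighted statistic): hits increment by
$|s|^w / \sum_{hits} |s|^w$, misses decrement by $1/(N - N_{hit})$, and
the ES is the signed maximal deviation. On an exact tie between the
positive and negative extremum, the extremum reached first along the
ranking wins (the walk-order convention).

Because the ranking statistic is a per-gene scalar, the null is generated
by gene-label permutation: set positions are redrawn uniformly,
`n_perm` times, shared across sets of equal size. The permutation p-value
is add-one against the same-sign half of the null — this is what makes a
random set's p uniform; dividing by all permutations would double the
null rate. NES divides the ES by the mean |null ES| of matching sign, and
the FDR q pools signed null NES across sets (the standard same-sign
pooling estimator, capped at 1). Set members absent from the ranking are
dropped and the used size reported; sets outside `[min_size, max_size]`
(defaults 10, 500) are skipped.

## Concordance between quantifications

`compute_tpm()` implements both conventions that matter in practice:
true TPM (counts scaled by feature length, then to one million per
sample) and the CPM-style variant without length normalisation that
long-read pipelines effectively report. Per-sample Pearson correlations
are computed over the feature intersection — features absent from one
matrix are dropped, not zero-filled, since zero-imputation inflates
correlation — on log2(x+1) by default (`raw` reproduces untransformed
correlations). Two correlations are compared with the Fisher-z test
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.

Distributional similarity uses the Jensen–Shannon divergence in base 2
(0 iff identical, at most 1), computed per sample on the gene-probability
vector (abundances normalised to sum to 1). The upstream description does
not state which distribution was compared; the per-sample gene-probability
convention is the reading adopted here.

Length/GC bias diagnostics regress per-gene mean log2(TPM+1) on
log10(length) or GC fraction. Note the arithmetic: if counts are
*independent* of length (as in direct RNA sequencing, one read per
molecule), length-normalising induces a negative trend of slope
$-\log_2 10$; if counts are proportional to length (short-read cDNA),
normalisation removes the trend exactly. The diagnostics are therefore
interpreted jointly with the `length_normalized` flag.

## Differential transcript usage

Counts are filtered DRIMSeq-style (defaults 12/4/10/10: a transcript
needs ≥10 reads in ≥4 samples, its gene ≥10 reads in all 12 samples;
genes keeping fewer than two transcripts are dropped). Fractional
quantifier outputs are rounded with a warning, as the likelihood needs
counts.

The gene test is a Dirichlet-multinomial likelihood ratio: null, one
proportion vector for all samples; alternative, one per condition. A
**common precision** is profiled by maximum likelihood under the null and
then held fixed for both hypotheses, so the statistic compares
proportions only and is referred to $\chi^2_{K-1}$. This choice is
deliberate: re-estimating precision freely under both hypotheses lets the
null soak up between-condition differences as overdispersion and was
measurably liberal at 6+6 samples, while the fixed-common-precision LRT
is calibrated. Unlike DRIMSeq there is no moderation of precision across
genes — estimation is per gene, simpler and well-defined, and its
calibration is what the test suite verifies. A `precision` argument
evaluates the test at a fixed value; as precision grows the statistic
converges to the multinomial LRT. Per-transcript tests collapse each
transcript against the aggregate of the rest (df = 1); at two transcripts
both collapse to the gene test, as they must.

Stage-wise error control follows the screen-and-confirm scheme: stage one
BH-adjusts gene p-values at the target OFDR (0.05); stage two adjusts
transcript p-values within each screened gene by Holm with Shaffer's
improvement — the sum-to-one constraint makes a single changed transcript
impossible, so the leading multiplier is $K-1$ and at $K = 2$ no
correction applies — scaled by $m/R$ (genes tested over genes screened).
Only two-condition designs are supported; multi-group contrasts are out
of scope.

## Numerical and reproducibility choices

* All stochastic stages consume integer seeds; stage-specific streams are
  derived with a Lehmer-style multiplier and stay inside 32-bit range.
  Identical configuration and seed reproduce every result TSV byte for
  byte (`run_pipeline()` writes MD5 checksums into its manifest).
* DM optimisation uses L-BFGS-B on softmax-parametrised proportions and
  log precision, bounded (logits ±30, log precision in [−10, 30]); the
  alternative starts from the null solution so the likelihood ratio is
  non-negative by construction. Non-convergence is flagged and yields a
  missing p-value.
* The LMM fallback threshold treats a residual standard error below
  1e−10 as degenerate (zero residual variance) and errors rather than
  reporting an infinite t.
* Histogram modes use a 1-nt histogram smoothed with a ±2 nt moving
  average — deterministic, unlike kernel density estimates.
* Validation problem sizes (the package's own choices): 2,000 genes for
  null calibration of both the DP and DM tests; 1,000 genes with 50
  injected effects for recovery at 40 reads per sample; 100 bootstrap
  replicates; 999 permutations for GSEA calibration and 200 for power
  repetitions; 5,000 genes for platform-correlation recovery.

## Known limitations

The χ² and t reference distributions are asymptotic; at 6+6 samples the
suite verifies their calibration empirically rather than assuming it.
Gene assignment of reads is taken as given (reference-name or interval
map); no re-alignment or tail re-estimation is performed. The DP model
assumes a common read-noise variance across conditions within a gene.
GSEA q-values inherit the known conservatism/anticonservatism trade-offs
of the same-sign pooling estimator at small set collections.
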