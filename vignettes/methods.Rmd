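---
title: "Models and methods behind pegscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pegscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegscreen)
```

pegscreen implements the hit-calling procedure of a FACS-sorted,
positive-selection CRISPR/Cas9 knockout screen and the companion
imprinted-DMR methylation analysis. This vignette explains the models, the
parameters that matter, the numerical conventions, and what the built-in
synthetic-data generator does and does not emulate.

## The screen model

The experimental design the statistics assume: a mutagenized cell pool
carrying one integrated sgRNA per (haploid) cell is stained for a reporter
protein that is silent in unperturbed cells, and a small reporter-positive
fraction (~0.5 % of stained cells) is recovered by FACS, alongside a
comparable reporter-negative fraction and an unsorted control. Guides that
disrupt a repressor of the reporter are over-represented among sorted
cells; everything else passes through a severe sampling bottleneck.

Two structural consequences drive the analysis design:

* **Sparsity.** The sorted samples contain a few cells per guide, so
  counts are noisy and many guides drop out entirely. Per-guide evidence
  is therefore aggregated per gene with a robust (outlier-trimmed median)
  statistic rather than a per-guide test.
* **Negative drift.** Renormalization within the sorted sample means that
  when a minority of guides is strongly enriched, *every other* guide's
  relative abundance falls: most genes end up with a negative log2 fold
  change. The per-gene medians are therefore centered by subtracting the
  library-median score, putting "no effect" at 0 on the reported scale.
  The realized offset is data-dependent and is logged by the fit; the
  candidate threshold (default 1.4) applies on the centered scale.

### Stage by stage

1. **Normalization** (`normalize_counts`). Reads per million with a
   pseudocount: `(count + c) / (colsum + c·L) · 1e6`, default `c = 0.5`.
   The pseudocount keeps all normalized values positive so every log fold
   change is finite; an all-zero sample column is a hard error.
2. **Per-sgRNA log2 fold change** (`sgrna_log2fc`). The ratio of
   replicate means of normalized values, sorted vs unsorted, computed
   within one immunostaining experiment at a time. This is a deliberate
   simplification: the original workflow ran a count-based
   differential-abundance tool merely to obtain per-guide log2 fold
   changes, and any consistent shrinkage-free estimator feeds the
   downstream gene statistic equivalently. It is the package's single
   deviation from the published workflow and is confined to this stage.
3. **Gene scores** (`gene_scores`). Pool each gene's values across
   experiments (~sgRNAs × experiments values), remove Tukey-hinge
   outliers, take the median, then center across genes. Genes with fewer
   than 3 surviving values are flagged `low_confidence`; genes with no
   fold-change records are excluded and reported.
4. **KS p-value** (`gene_ks_test`). Two-sample, two-sided
   Kolmogorov–Smirnov test of the gene's pooled values against the pooled
   background of all sgRNA values. The gene's own values stay in the
   background by default: with ~10–20 of ~10⁴–10⁵ values the contamination
   is negligible, and including them keeps the background identical for
   every gene (an `exclude_self` flag is available). The comparison's
   second sample is a declared choice — the original description does not
   pin it down.
5. **Candidate calling** (`call_candidates`). All four filters must pass:
   centered log2FC > 1.4; KS p < 0.05 (unadjusted — by design, no multiple
   testing correction is applied to the filter, though a BH-FDR column is
   emitted for reference); TPM > 1 in the reference expression sample;
   and no enrichment in the reporter-negative sort (centered log2FC > 0.5
   with p < 0.05 there discards the gene). The negative-sort cut is
   applied on the *centered* scale of the negative-sort score table for
   symmetry with the positive filter; a flag switches to the raw scale.
6. **Annotation enrichment** (`annotation_enrichment`). Fisher's exact
   test on the candidate × annotated 2×2 table over the library universe;
   the sample odds ratio `ad/bc` is reported (±∞/0 on zero margins), not
   the conditional MLE.

## Numerical conventions

* **Outlier rule.** `remove_outliers` uses median-of-halves Tukey hinges
  (the five-number-summary convention), not interpolated quantiles,
  because that is the documented behavior of the classic boxplot
  statistics rule it reproduces. The whisker coefficient is 1.5. A
  constant vector is returned unchanged, and the hinges always bracket
  the median, so trimming can never empty a gene.
* **KS p-values.** Exact permutation null (tie-aware) when
  `n·m ≤ 10 000`; otherwise the asymptotic Kolmogorov distribution with
  the Stephens finite-sample correction
  `D·(√nₑ + 0.12 + 0.11/√nₑ)`, `nₑ = nm/(n+m)`. The plain limit is
  noticeably conservative at the ~20 values per gene this design
  produces; the corrected form keeps null p-values uniform. D is computed
  over the union of observed points with step ECDFs, so ties are handled
  by construction.
* **Degenerate inputs.** Empty fold-change sets, all-zero sample columns,
  empty libraries, and KS calls with an empty sample are errors, not NA
  propagation. A paired t-test on a constant non-zero shift returns a
  decisive p (0 or 1 by direction) rather than failing, since the t
  statistic diverges.
* **Determinism.** Every generator is a pure function of (arguments,
  seed). One master seed yields per-sample child seeds via a single
  `sample.int` draw, giving sample-level independence with end-to-end
  reproducibility; candidate calling is order-invariant.

## The synthetic-data generator

`simulate_screen_counts` draws latent per-guide abundances from a Gamma
with mean 1 and variance `baseline_dispersion` (default 0.3), so unsorted
sequencing (a multinomial over abundances) has negative-binomial-like
marginals. Reporter-positive samples first pass a multinomial bottleneck
of `sorted_fraction · cells_per_replicate` cells — with guide weights
multiplied by `enrichment_factor` (default 10) for guides of the
`n_true_regulators` planted genes — then a multinomial sequencing draw of
`reads_per_sample` reads. Reporter-negative samples share the bottleneck
without the enrichment weighting.

Defaults mirror the study regime scaled to desk size: 1 000 genes × 10
sgRNAs, 2 experiments × 2 replicates per condition, `sorted_fraction`
0.005, staining coverage 830× the library (so the bottleneck is a few
cells per guide), and sequencing at 200× library coverage (within the
100–800× band of the real screen). The dispersion default is a free
parameter — the real library's abundance dispersion is not reported — and
is *not* an estimate of any particular library.

What the generator deliberately omits: multi-infection (MOI > 1),
antibiotic-selection dynamics, growth-rate differences among mutants,
haploid/diploid conversion, PCR jackpotting and sequencing error. Passing
the planted-recovery tests therefore demonstrates that the statistics
recover the signal their own model generates under realistic sparsity —
not that the pipeline is robust to every artifact of real screens.

`simulate_methylome` places CpGs every 10 bp inside each DMR, draws
control β from Beta(17, 3) (maternal, mean 0.85) or Beta(3, 17)
(paternal, mean 0.15), a bimodal mixture in the background, and builds the
treated sample from the *same* draws with target DMRs shifted down by
`hypo_delta` (clamped to [0, 1]). This matched-pair design isolates the
aggregation and delta arithmetic from generator noise; recovery tests
exercise correctness of the bookkeeping, with the only stochastic bias
coming from clamping at high planted deltas. `simulate_expression` gates
each gene as expressed with probability `expressed_fraction`, giving
truncated log-normal TPM > 1 or uniform TPM in [0, 1).

In the end-to-end recovery and null-calibration runs, expression is
generated with `expressed_fraction = 1`: the TPM gate encodes a biological
prior (an unexpressed gene cannot be a reporter repressor in this assay),
and letting it randomly veto planted genes would measure the generator,
not the statistics. The gate itself is exercised by dedicated unit tests.

## The methylation analysis

DMR coordinates use BED convention (0-based, half-open); a CpG at start
`s` belongs to `[a, b)` iff `a ≤ s < b` (membership via GenomicRanges).
DMR means are unweighted across CpGs — "mean over all CpGs of the region"
— with a coverage-weighted variant behind a flag. A DMR needs `min_cpgs`
(default 3; an RRBS noise guard, not a literature constant) member CpGs
for a defined mean.

The informative-DMR filter *drops* maternal DMRs with control mean < 0.6
and paternal DMRs with control mean > 0.4; boundary values are retained
because the drop rule is strict. The filter is idempotent.

The global hypomethylation contrast pairs β per CpG across the two
samples (CpGs missing from either side are dropped) and applies a
one-tailed paired t-test — pairing by CpG, not by sample, is the declared
reading of the original contrast.

PEG response classification uses two configurable cut-offs:
`demeth_delta_cut = −0.2` (Δβ at or below ⇒ demethylated) and
`activation_fc_cut = 2` (expression fold change at or above ⇒ activated).
These defaults are *not* published constants — the original analysis
reports the categories but no thresholds — so the reported category table
always carries the thresholds used, and no claim is made that the
defaults reproduce any particular published split.

## Problem sizes used by the test suite

The suite validates the statistical primitives against brute-force
oracles (exhaustive KS permutation enumeration for all sample-size pairs
with n·m ≤ 60, hinge enumeration on 1 000 random vectors, hypergeometric
tail sums on random 2×2 tables), calibrates the null on a 1 000-gene ×
10-sgRNA × 2-experiment screen, and measures planted-hit recovery over
10 seeded simulations of the same size with 20 planted regulators at
enrichment 10. Methylation-delta recovery runs a 4 × 100 seed grid with
25 CpGs in the target DMR. These sizes are the package's chosen
validation conditions; the statistics themselves have no scale limit
beyond memory.

## Known limitations

* The per-guide fold-change estimator is a ratio of replicate means with
  a pseudocount; it does not model count dispersion, so very low-coverage
  designs will see more variance than a shrinkage estimator would give.
* The KS background includes all guides, so a screen where a large
  fraction of genes is truly enriched would deflate sensitivity (the
  background absorbs signal); the design assumes hits are rare.
* The centered threshold 1.4 encodes a particular raw-to-centered
  equivalence (0.5 ↔ 1.4 at a global offset near −0.9) that is
  dataset-specific; both scales are exposed and the realized offset is
  always reported, but users of differently-bottlenecked screens should
  inspect the offset before trusting the default.
* The response classification thresholds are defaults, not estimates; the
  category boundaries are sharp although the underlying biology is not.
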