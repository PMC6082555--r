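---
title: "Gene-wise normalization and empirical false-positive control for RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise normalization and empirical false-positive control for RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqpgq2)
```

## The problem

Bulk RNA-seq differential expression pipelines must trade sensitivity
against specificity. Global per-sample normalizations (total count, upper
quartile, median-of-ratios) leave the gene-wise scale untouched, and count
models can then be anti-conservative for very high-count genes —
residual rRNA and other abundant species that survive library depletion
skew the upper tail of the count distribution. In clinical cohorts (the
motivating application is breast-cancer subtype profiling, tumors versus
adjacent normal tissue) false-positive marker genes are costly, so this
package centers the analysis on two specificity devices: a gene-wise
second normalization stage, and an *empirical* fold-change cutoff chosen
so that a null comparison produces (almost) no calls.

## Models and procedures

### UQ-pgQ2 normalization

Stage 1 (per sample): divide each sample's counts by its 75th percentile
over genes, computed with linear interpolation between order statistics
(`stats::quantile` type 7). The percentile definition is fixed for
bit-reproducibility; the upper quartile is taken over all genes that
survive the global all-zero filter, including zeros in that sample, which
is standard upper-quartile practice (an option restricts it to positive
counts). Stage 1 makes the values exactly invariant to per-sample
rescaling of the raw counts.

Stage 2 (per gene): divide by the gene's across-sample median of stage-1
values (Q2) and multiply by a scale constant $K$ (default 100), so every
gene with a positive stage-1 median has across-sample median exactly $K$.
Stage 2 rescales whole gene rows by constants, so it preserves every
between-group log fold change identically — its effect is on the
*variance model*, equalizing the scale at which genes enter the NB test.
Genes whose stage-1 median is zero (expressed in fewer than half the
samples) fall back to the smallest positive stage-1 value as divisor and
are flagged; this preserves zeros and keeps all values finite. The choice
of $K$ is immaterial to the Wald statistic — it is absorbed into the gene
mean — and 100 simply keeps values count-like.

Values destined for the count-model test are rounded half-to-even to
integers and tested with all size factors equal to 1. Rounding changes
each value by at most 0.5 on a scale where expressed genes sit near 100,
a relative perturbation well below the test's standard errors.

### Median-of-ratios size factors

The second route uses the standard median-of-ratios construction: over
genes positive in all samples, a per-gene reference is the geometric mean
of its counts; a sample's size factor is the median ratio of its counts to
the references. Factors are rescaled to geometric mean 1 (tolerance 1e-9)
so that "size factor 1" means "average depth", and raw counts are tested
with these factors.

### Dispersion estimation

For a two-group design the NB group-mean estimates have closed form
($\hat\mu_k = \sum_{j \in k} x_{gj} / \sum_{j \in k} s_j$), so all fits are
vectorized over genes; no per-gene IRLS is needed. Three steps:

1. **Gene-wise:** maximize the Cox–Reid-adjusted NB profile likelihood in
   $\alpha$ per gene by golden-section search on $\log\alpha$ (bracket
   $[10^{-8}, \max(50, 10\,\hat\alpha_{\mathrm{MoM}})]$, tolerance $10^{-6}$
   on $\log\alpha$), with a within-group method-of-moments estimate
   seeding the bracket. The CR term $-\tfrac12 \sum_k \log \sum_{j\in k} w_j$
   with $w = \mu/(1+\alpha\mu)$ corrects the bias from estimating two group
   means.
2. **Trend:** $\alpha(\mu) = a_0 + a_1/\mu$ fitted by iteratively
   reweighted least squares (gamma-style weights $1/\mathrm{fitted}^2$,
   coefficients clamped non-negative) over genes with gene-wise dispersion
   above the $10^{-8}$ floor, with one outlier-trim pass removing genes
   whose absolute log residual exceeds 2 MAD, then refitting. With fewer
   than 10 usable genes the trend falls back to a constant median with a
   warning.
3. **Shrinkage:** the final per-gene dispersion maximizes the CR-adjusted
   likelihood plus a log-normal prior centered at the trend. The prior
   standard deviation is the MAD of the log residuals, floored at 0.25 so
   that shrinkage never becomes degenerate when the gene-wise estimates
   happen to hug the trend.

Floors: dispersion $10^{-8}$ (numerical, far below any biological value),
prior SD 0.25.

### The Wald test

log2 fold change is the unshrunken ratio of closed-form group means;
its standard error comes from the NB GLM Fisher information,
$\mathrm{SE} = \sqrt{1/\sum_{j\in\mathrm{ref}} w_j +
1/\sum_{j\in\mathrm{test}} w_j}/\ln 2$ (at the MLE the observed and
expected information coincide, which is what the oracle test verifies
against a numerical Hessian). Two-sided p-values come from the standard
normal and are Benjamini–Hochberg adjusted (missing p-values are excluded
from the number of tests). A group with zero counts for a gene is floored
at $0.5/\mathrm{median}(s_j)$ and the gene flagged — flagged genes are
reported, never silently dropped; no independent filtering or outlier
deletion is applied because the calling rule (below) already guards
specificity. Reported fold changes carry no shrinkage prior: the cutoff
rule operates on plain |log2FC|, and mixing a shrunken estimate with an
empirically selected cutoff would conflate two regularizations.

### Mock within-group comparisons and cutoff selection

Samples of one condition are partitioned uniformly at random into halves
of sizes $\lceil n/2\rceil, \lfloor n/2\rfloor$; the full route
(normalize, test, adjust) runs on each of 10 partitions, and genes with
$\mathrm{padj} \le 0.05$ and $|\mathrm{log2FC}| \ge c$ are counted for each
grid value $c \in \{1, 1.5, 2, 2.5, 3\}$. All calls are false positives by
construction; FPR% is the mean count over repetitions divided by the
number of genes tested, times 100. Partitions are not forced to be
distinct across repetitions (collision probability is negligible for
$n \ge 20$); per-repetition seeds derive from the master seed by a fixed
counter scheme and are recorded for audit. Normalization is computed once
per condition — it does not depend on the split labels — so repetitions
differ only in the test.

The *base* cutoff is the smallest grid value with FPR ≤ 0.05% (the
working criterion); the *max* cutoff is the smallest with FPR ≤ ε, default
ε = 0.005% (≤ 1.7 expected false calls in a 35,203-gene universe). ε is an
explicit parameter rather than a hard-coded rule because "approximately
zero" admits no single threshold consistent across published uses; both
selections return an explicit unsatisfied flag when no grid value
qualifies. When tumor-side and control-side reports are both available,
the conservative default is to require the threshold on the maximum FPR
across reports.

### The combining rule

Two routes (UQ-pgQ2 with unit factors; raw counts with median-of-ratios
factors) are run at the same FDR. Genes called by both are accepted.
A gene called by exactly one route is accepted only when *that route's*
fold-change estimate is at least the route's max cutoff (inclusive ≥ —
each route's normalization yields its own fold change, so a route's
unique genes are judged by its own estimate). Provenance is recorded per
gene and the partition invariant (three disjoint classes summing to the
total) is asserted on every run. Per-comparison base cutoffs may differ
between routes and are always explicit parameters, never inferred.

## The simulator: what it emulates and what it does not

`simulate_counts()` draws $x_{gj} \sim \mathrm{NB}(s_j\,\mu_g\,
2^{\beta_g 1[j \in \mathrm{group\,2}]}, \alpha_g)$ with log-normal
baseline means (default meanlog 4, sdlog 2, spanning sub-count to
$10^4$-count genes), a dispersion trend $\alpha = 0.05 + 5/\mu$ or a
constant, uniform library-size factors in $[0.5, 2]$, a DE fraction whose
realized gene count is exact, discrete |log2FC| magnitudes
$\{1.5, 2, 3\}$ aligned with the cutoff grid, and 1% contaminant genes
with mean × 50 and dispersion × 4 as a stand-in for residual rRNA — a
caricature, not calibrated to real rRNA content. A truth table
accompanies every matrix. `n2 = 0` produces a single-condition matrix for
within-group null studies.

What it does *not* model: correlated genes, batch effects, sample-quality
gradients, isoform structure, or the heavy non-NB tails of real clinical
cohorts. Passing tests therefore demonstrate correctness of the
procedures under the NB model and calibrated specificity on idealized
nulls, not performance claims about any particular real dataset.

## Design choices in open territory

* **Native two-group Wald test.** Both routes must run through the same
  test — one on pre-normalized rounded counts with unit factors, one on
  raw counts with size factors. A single closed-form implementation keeps
  the routes uniform and separately testable against an independent
  likelihood-optimizer oracle; an off-the-shelf fitter is used only as a
  cross-check (size factors against DESeq2's implementation), never as
  the code path.
* **Route ordering on synthetic nulls.** Because one uniform test serves
  both routes, the two routes' null FPRs at cutoff 2 are both essentially
  zero at realistic split sizes (21 samples and up), and which route shows
  the odd single false call is noise; at very small splits the gene-wise
  route is slightly *less* specific, reflecting its known weakness for
  genes below the 25th count percentile (the scale-up of low-count genes
  makes their rounded pseudo-counts look more precise than they are). The
  property the package guarantees — and tests — is the 0.05% specificity
  bound for both routes at cutoff 2 under the null.
* **Calibration test scenario.** Wald p-value uniformity is checked on
  moderately expressed genes (baseline meanlog 5, sdlog 1, 4000 genes,
  equal library depth). For very low counts the test statistic is
  discrete and no normal-referenced p-value is uniform; and under strongly
  unequal depths the closed-form moment estimator of the group mean is
  mildly inefficient relative to the information bound, a deliberate
  trade for closed-form speed that a 20,000-gene KS test can detect while
  the 0.04–0.06 type-I band still holds.
* **Zero-median fallback, mean floors, inclusive thresholds** are each
  chosen to keep every gene reportable and every rule reproducible from
  the output tables alone (no hidden filtering).
* **Gene IDs are opaque strings.** No Ensembl version stripping unless
  requested (`strip_gene_version`), avoiding silent ID collisions; the
  all-zero filter is applied once across all loaded samples jointly, not
  re-applied per comparison subset.

## Problem sizes used in validation

The shipped validation suite exercises: the within-group procedure at
20,000–24,000 genes × 42 samples × 10 splits (the scale at which the
0.05% criterion is meaningful — one false call in 20,000 genes is already
0.005%); dispersion recovery at 2,000 genes; calibration at 4,000 genes;
and end-to-end recall at 5,000 genes with 300 spiked 8-fold genes
(recall ≥ 0.9 at observed FDR ≤ 0.1). These sizes were chosen as the
smallest at which each property is statistically meaningful.

## Known limitations

* Two-group designs only; no covariates, paired structures, or
  likelihood-ratio tests.
* The low-count regime of UQ-pgQ2 inherits the method's documented
  anti-conservativeness for genes expressed well below the upper
  quartile; the fold-change cutoff, not the p-value, is the effective
  guard there.
* The empirical cutoff depends on the within-group sample size: smaller
  conditions give noisier splits, larger selected cutoffs, and hence
  lower sensitivity. This is a property of the procedure, not a bug.
* ε ("FPR ≈ 0") is a convention; published max-cutoff tables are not all
  consistent with a single ε, which is why it is exposed as a parameter.
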