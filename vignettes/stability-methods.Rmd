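---
title: "Measuring gene expression stability in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene expression stability in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segstab)
```

## The problem

Bulk transcriptomics defines housekeeping genes as genes expressed at steady
levels across tissues — but a steady *population average* says nothing about
behaviour in individual cells. Single-cell RNA-seq shows that expression is
often bimodal: a gene is "on" (with some cell-to-cell variability) in part of
the population and effectively "off" — or technically dropped out — in the
rest. A gene that is a useful control at single-cell resolution must be
unimodal, tightly distributed, rarely zero, and indifferent to cell type.
`segstab` quantifies these four properties per gene and aggregates them into
one stability index.

## Model and features

Zeros are set aside first; for the strictly positive log2-scale values
\(x\) of a gene across cells we fit

\[
f(x) \;=\; \lambda\,\frac{\beta^{\alpha}}{\Gamma(\alpha)}x^{\alpha-1}e^{-\beta x}
\;+\; (1-\lambda)\,\frac{1}{\sigma\sqrt{2\pi}}\,e^{-\frac{(x-\mu)^2}{2\sigma^2}},
\qquad 0 \le \lambda \le 1 .
\]

The Gamma density is anchored at the low end of the distribution and absorbs
the residual low/"off" signal; the Gaussian describes the expressed state.
Zeros cannot enter this likelihood (the Gamma density is undefined at 0) and
carry a different kind of information, so they are summarized separately:

* \(\omega\) — the fraction of cells reporting exactly zero;
* \(\omega^\* = \omega \cdot \mathrm{minmax}(\mu)\) — the zero fraction
  down-weighted by the gene's min–max-scaled Gaussian mean. Dropout is biased
  toward lowly expressed genes, so a raw \(\omega\) would punish low
  expression twice; multiplying by the scaled mean removes that bias. The
  scaling is across genes, onto \([0,1]\), with the convention that a
  constant vector maps to zeros. (Scaling \(\mu\) — rather than \(\omega^\*\)
  itself — is the reading that realizes the stated purpose of the
  regularization; the alternative would be circular.)
* \(F\) — when predefined cell classes are available, the one-way ANOVA
  F-statistic of the gene across classes, computed on *all* cells including
  zeros: class-specific dropout is genuine cell-type signal and must count
  against stability. Classes with fewer than two cells are dropped once per
  dataset. Degenerate cases follow fixed conventions: no variation at all
  gives \(F = 0\) (maximally stable by this feature); zero within-class
  variance with nonzero between-class variance gives \(F = +\infty\), which
  ranks last.

A stable gene has small \(\lambda\), small \(\sigma^2\), small
\(\omega^\*\) and small \(F\).

### The stability index

Each feature is ranked across genes in increasing order (average ranks on
ties), ranks are rescaled to \([0,1]\) by \((r-1)/(G-1)\), and the index is
the mean of \(1 - \text{scaled rank}\) over the features used. The
orientation is chosen so that **larger index = more stable**, which makes
the selection rule below coherent; with four complete tie-free features the
index averages to exactly 0.5 by construction. Because the index depends on
features only through ranks, it is invariant to any strictly monotone
transformation of a feature and comparable across datasets whose feature
scales differ. When no class labels exist the index averages the three
label-free features; the pipeline log records the 3-feature mode.

### SEG selection

A gene is selected when its index rank percentile strictly exceeds 80 *and*
its reversed rank percentile strictly exceeds 60 for every feature
(percentile \(= 100 (r-1)/(G-1)\); "reversed" means features ranked in
decreasing order, so small values score high). The second condition prevents
a gene from coasting on three excellent features while being mediocre on the
fourth. Both comparisons are strict; the thresholds are tunable and the
index itself is continuous, so users needing a fixed-size control set can
simply take the top-\(k\) genes by index. Lists from multiple datasets of
one organism are merged with `union_gene_lists()` (set union, first-seen
order).

## Fitting: EM, initialization, degeneracies

The mixture is fitted by EM with a deterministic initialization: values are
split at the 25th percentile; the Gamma component starts from
method-of-moments on the lower part, the Gaussian from the mean/variance of
the upper part, and \(\lambda_0\) is the lower-part fraction clamped to
\([0.05, 0.95]\). The Gamma M-step maximizes the weighted likelihood with a
Newton iteration on the shape (digamma/trigamma); the rate follows from the
weighted-mean identity. Convergence is declared when the relative
log-likelihood change falls below \(10^{-8}\) (at most 1000 iterations);
\(\sigma^2\) is floored at \(10^{-6}\) and the Gamma shape and rate at
\(10^{-4}\) to prevent component collapse. The log-likelihood trace is
stored on every fit, and the suite asserts it never decreases. Genes with
fewer than 20 positive values, or fewer than 3 distinct ones, are flagged
invalid rather than aborting a run.

One genuine subtlety: when a gene's positive values are **unimodal** the
mixture likelihood is nearly flat in \(\lambda\) — a high-shape Gamma can
imitate a Gaussian — and the EM endpoint becomes an artifact of the
initialization (in experiments, \(\hat\lambda\) drifted to 0.3–0.45 on pure
Gaussian samples). Since a unimodal profile is precisely the stable case,
reporting an arbitrary \(\lambda\) would corrupt the feature. Each fit
therefore ends with a nested-model guard: if the five-parameter mixture
fails to beat the two-parameter single-component fit by the BIC margin
(\(2\Delta\ell < 3\log n\)), the boundary fit \(\lambda = 0\) is reported
with the single-component parameters, flagged `reduced`. The same guard
(against a single Gamma) applies to the Gamma–Gamma family. This also gives
the clean limit behaviour that shifting all values by a constant shifts
\(\hat\mu\) by exactly that constant when the Gamma component is empty.

Model families are compared with \(\mathrm{BIC} = k\ln n - 2\ell\), \(k=5\)
for either family (\(\lambda\) plus two parameters per component); the
smaller BIC wins and exact ties go to Gamma–Gaussian. On data simulated from
either family at \(n = 1000\), the generating family is recovered in
roughly 90% of genes.

## Evaluating gene-list stability

The stability of a gene list is audited by clustering: restrict the
log-expression matrix to the list's genes, run k-means over cells with
\(K\) equal to the number of predefined classes, and score the clustering
against the classes. From the pair counts \(a, b, c, d\) over all
\(N(N-1)/2\) cell pairs (same/different class × same/different cluster):

\[
\mathrm{ARI} = \frac{2(ad-bc)}{(a+b)(b+d)+(a+c)(c+d)},\qquad
\mathrm{Jaccard} = \frac{a}{a+b+c},\qquad
\mathrm{FM} = \sqrt{\frac{a}{a+b}\cdot\frac{a}{a+c}},
\]

and Purity is the summed best-class overlap per cluster divided by \(N\).
The ARI is implemented exactly in this pair-count form (the package's
reported numbers come from it, and the tests cross-check the counts against
brute-force pair enumeration). Degenerate denominators follow documented
conventions (identical-partition limits give 1; empty-intersection limits
give 0). A *stable* list is one whose clustering shows **low** concordance:
its genes carry no cell-type signal. Summary tables multiply by 100, the
convention such concordance tables are reported in.

k-means uses Euclidean distance on the gene-restricted log-expression
submatrix, cells as observations, with no per-gene standardization and no
dimension reduction — the list's genes *are* the feature space under audit,
and rescaling them would alter exactly the signal being measured. Each of
the (default 10) repetitions uses 10 random restarts, keeping the
best-inertia solution, with per-repetition sub-seeds derived from the master
seed; clustering is delegated to `stats::kmeans` (Hartigan–Wong), the
field-standard implementation, rather than a bespoke loop. Because list
length affects clustering, `size_matched_subset()` draws random size-matched
subsets so lists of different sizes can be compared fairly.

## Synthetic data: what it emulates, and what not

`simulate_seg_data()` draws, per gene, the generative parameters of the
mixture above plus a dropout model, and emits a raw-scale matrix
(back-transformed \(2^v - 1\), so `log_transform()` recovers the drawn
values exactly), class labels (near-equal multinomial), and the full truth
table. Dropout is coupled to expression as
\(\pi_g = \text{base}_g \cdot \mathrm{sigmoid}(-(\mu_g - m_0)/s)\) with
\(m_0 = 6\), \(s = 1.5\) (log2 units): lowly expressed genes lose more
values, which is the bias \(\omega^\*\) exists to correct. Stable genes
(defaults: \(\lambda \le 0.15\), \(\mu \in [6,10]\), \(\sigma \in
[0.4,0.9]\), baseline dropout 5–20%, no class shifts) contrast with variable
genes (\(\lambda \in [0.2,0.6]\), \(\mu \in [2,8]\), \(\sigma \in [0.8,2]\),
dropout 20–60%, Gaussian-mean class shifts with sd 1.5 log2 units —
moderate, cell-type-marker-like effects). These ranges were fixed once as a
realistic caricature of quantified scRNA-seq data. Gaussian draws falling
below 0 are clamped to 0 (sub-detection expression), which adds a small
excess of zeros for low-mean genes.

The generator deliberately omits library-size and batch effects, UMI-level
count noise, gene–gene correlation and doublets. Passing tests on this data
therefore demonstrates the estimator's correctness under its own model —
parameter recovery, ranking behaviour, selection logic — not robustness to
every artifact of real data; on real matrices the upstream quantification
and the user's quality control carry that burden.

## Problem sizes and measured behaviour

The test suite and the acceptance script run, among others: EM recovery
over 100 simulated genes at 1000 cells (mean absolute error ~0.01 in
\(\lambda\), ~0.03 in \(\mu\)); family selection over 100 genes per family
at 1000 cells; a full identification run at 1000 genes × 1000 cells with
20% stable genes and 4 classes (SEG precision 1.0 at the default
thresholds, and ARI near 0 for the stable set vs ~1 for an equally sized
class-informative set); and the subsampling protocol at 500 genes × 1000
cells, 10 replicates of 80% of cells (mean pairwise Pearson \(r \approx
0.99\)). These sizes keep a complete run in the low minutes on one CPU
while leaving all statistical conclusions comfortably away from their
thresholds.

## Known limitations

* \(\lambda\) recovery degrades for genes whose expressed component sits
  close to zero (\(\mu \lesssim 3\) log2 units): the clamped lower Gaussian
  tail and the Gamma component overlap, and part of the expressed mass is
  indistinguishable from "off". Such genes are rarely SEG candidates.
* The >80%-zeros gene filter is applied on the raw matrix before fitting
  (the zero set is identical on either scale); genes just above the
  boundary keep few positive values and fit noisily — the `valid` flag and
  `min_points` guard them.
* The F-statistic assumes the predefined classes are trustworthy; mislabeled
  classes dilute it toward the null.
* Cross-species comparisons require the user to map identifiers first; gene
  ids are opaque strings throughout.
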