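---
title: "Inferring regulatory networks from joint-expression histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from joint-expression histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

grnhist predicts whether a transcription factor (TF) regulates a candidate
target gene from the *joint* distribution of the pair's expression across
many biological conditions. The premise is classical — a regulator and its
target co-vary — but instead of summarizing co-variation into a single
coefficient, the pair's paired observations are binned into a 2D histogram
(TF expression on the first axis, target on the second, 32 bins per axis by
default). The histogram preserves the shape of the dependence: monotone
ridges, saturation, bimodality, and the zero-inflation structure typical of
single-cell data all survive binning, while a correlation coefficient would
collapse them to one number. Two histograms are computed per pair — one
from a bulk RNA-Seq matrix (diversity across samples) and one from a
single-cell RNA-Seq matrix (diversity across cells within an individual) —
and stacked vertically into a 64 x 32 image. A small convolutional network
scores the image: six 3 x 3 convolutional layers (rectifier activations)
with 2 x 2 max pooling after layers 2, 4 and 6, a flatten, two hidden dense
layers (128 and 64 units) and a single sigmoid output. The output is a
score in [0, 1]; values near 1 indicate a likely interaction. Supervision
comes from a gold standard of labeled TF-target pairs (1 = regulates,
0 = no interaction).

A genome-wide network is assembled by scoring every TF x candidate pair
and thresholding, either by retaining the top fraction of scores (default
10%, reporting the implied score cutoff) or by a fixed score cutoff
(strictly greater than, default 0.5). Both conventions are in field use
and both are provided; the top-fraction route is the default because it
fixes the network size rather than an arbitrary probability.

## Why a CNN, and how it is implemented here

The network has to read spatial structure out of the histogram; a
convolutional stack is the standard tool for that and needs very little
capacity at 64 x 32 resolution. No deep-learning framework is declared as
a dependency: the package carries a compact, fully deterministic CNN
engine (`R/nn.R`) in which convolutions are expressed as im2col gathers
followed by BLAS matrix products, with backpropagation and Adam written
out explicitly. This keeps training exactly reproducible under a single
integer seed (R's RNG drives initialization, shuffling, and the
validation split; no threaded nondeterminism is involved) and keeps the
dependency surface minimal. Training a 280-image corpus for ten epochs
takes on the order of a few minutes on one CPU core.

Hyperparameters the gold-standard literature leaves open (filter counts,
kernel and pool sizes, dense widths, optimizer, learning rate, batch
size, early stopping) are set to the minimal conventional choices for
this layer inventory — filters 32/32/64/64/128/128, 3 x 3 kernels,
2 x 2 pools, dense 128/64, Adam at 1e-3, batch 32, early stopping on
validation AUROC with patience 5 — and every one of them is exposed in
`model_config()`. Two interpretation choices are worth stating: "two
dense layers and a final sigmoid layer" is read as two *hidden* dense
layers plus a separate 1-unit sigmoid output; and the decision threshold
uses strict `>` so a score exactly at the cutoff is called negative.

## Featurization choices

* **Bin ranges.** Each gene's minimum and maximum within a modality
  define its histogram range. TPM dynamic ranges differ by orders of
  magnitude across genes, so fixed global ranges would park most genes in
  a corner of the image; per-gene ranges also make the featurization
  invariant to rescaling the expression matrix. The consequence — images
  do not encode absolute expression level — is intentional: the
  classifier should read the *shape* of the joint distribution.
* **Count transform.** Histogram counts are mapped through log10(1 + c)
  by default. A 17,000-cell block otherwise dwarfs a 700-sample block
  numerically; the log keeps both blocks on comparable scales. Raw counts
  remain available (`count_transform = "raw"`), and the conservation
  invariant (each raw block sums to its modality's sample count) is
  tested in that mode.
* **Orientation and stacking order.** TF on the first axis, bulk block on
  top. Nothing in the method depends on the convention; it only has to be
  identical between training and scanning, which the histogram config
  carried in the model checkpoint enforces.
* **Expression preprocessing.** Per-million scaling (TPM when gene
  lengths are supplied, CPM otherwise) followed by log10(1 + x). The log
  transform is applied to both modalities by default — only the
  single-cell transform is strictly required by the zero-inflation
  argument, but transforming both keeps the two blocks on comparable
  scales; callers who want untransformed bulk simply skip
  `log_transform()` on that matrix, since the pipeline is composed from
  functions rather than driven by flags.

## The synthetic-data generator

Real evaluations of this class of method train on curated gold standards
against population-scale bulk data (hundreds of natural accessions) and
root-tissue single-cell atlases (tens of thousands of cells). Those
accessions are deliberately not downloaded here; instead
`simulate_paired_dataset()` emulates the statistical structure the method
exploits, so that every downstream stage is testable:

* each TF has a latent log-activity drawn per sample and per cell from
  Normal(3, 1) (natural-log scale, i.e. median expression ~e^3 ≈ 20);
* each of its targets tracks that activity linearly on the log scale with
  slope `effect_slope` (default 2);
* bulk values are log-normal around the gene's log-mean with noise sd
  0.2;
* single-cell values are negative-binomial counts (size 2) around the
  same log-mean, then zeroed with probability 0.3 (Bernoulli dropout),
  reproducing the sparse, over-dispersed, zero-inflated character of UMI
  matrices;
* decoy genes follow the same marginal model but are independent of every
  TF. Labels pair each TF with its own targets (positives) and an equal
  number of uniformly sampled (TF, decoy) pairs (negatives). Cross pairs
  (TF_i, target-of-TF_j) are excluded from negatives to keep labels
  unambiguous.

The defaults — 40 TFs x 5 targets + 200 decoys, 200 bulk samples, 500
cells, 400 labeled pairs — are the study conditions used by the test
suite and the acceptance script. They were chosen once as a realistic
small-scale regime: sample and cell counts are an order of magnitude
below the real datasets (enough for stable histograms at 32 bins), and a
slope of 2 with noise sd 0.2 gives planted pairs a clearly higher rank
correlation than decoys without making the marginal distributions
distinguishable.

What passing tests do and do not show: the generator plants a *monotone,
single-latent-factor* dependence shared by both modalities. Real
regulation is confounded by indirect effects, shared upstream regulators,
cell-type composition and batch structure, none of which are simulated.
A high AUROC here demonstrates that the featurization preserves
co-expression structure and that the classifier can learn it — it is a
correctness check of the machinery, not an estimate of accuracy on real
gold standards. Conversely the label-shuffled null and the zero-slope
configuration verify that nothing in the pipeline leaks labels.

## Validation statistics

* **Permutation overlap null.** To ask whether a predicted network
  overlaps an experimental reference (ChIP targets, perturbation DE
  sets, Y1H or DAP-seq target lists) more than chance, each permutation
  replaces every TF's predicted target set with a uniform sample of equal
  size from the gene universe — a degree-preserving null, the minimal one
  consistent with reporting a per-comparison expected overlap. Expected
  overlap is the permutation mean (its closed form is
  sum_tf d_tf r_tf / N, which the test suite checks to 2% at 10,000
  permutations); fold enrichment is observed/expected; the empirical
  p-value is the strictly-greater count over permutations, displayed as
  "< 1/n" when zero. A +1-smoothed variant is deliberately not the
  default so that summary rows match the conventional definition.
* **Per-TF hypergeometric overlap.** For each TF present in both
  networks, the upper-tail hypergeometric probability of the observed
  target-set intersection given the universe, BH-adjusted across the
  table, significant at q < 0.05. The universe defaults to the aligned
  expression universe intersected with the reference space and is
  overridable — reported fractions are sensitive to it, which is why it
  is explicit everywhere.
* **GO-based function inference.** A TF is inferred to act in a
  biological process when that term is enriched (hypergeometric + BH,
  q < 0.05) among its predicted targets. Fifteen root-level BP terms are
  excluded up front because they annotate too broadly to be informative;
  the exclusion is asserted on every output. Candidate terms per TF are
  those annotating at least one target — testing the full ontology would
  only inflate the BH family with untestable terms. Annotations are used
  as-is, without ancestor propagation: whether upstream enrichment
  pipelines propagate is tool-dependent, and propagation would blur the
  recovery-rate statistic (the fraction of TFs carrying a term whose
  targets also recover it) that the annotate module reports.

## Numerical conventions and degenerate inputs

* Histogram bins are half-open [e_i, e_{i+1}) with the final bin closed,
  so in-range data conserve total count; a degenerate range (constant
  gene) widens to [lo, lo + 1] with a warning rather than failing a whole
  corpus.
* AUROC uses the Mann-Whitney rank formulation with ties counted 1/2 —
  exactly the trapezoidal ROC area, and exactly what the O(n^2)
  concordant-pair oracle in the tests computes.
* 0/0 metric cases (no predicted positives, no actual positives) are
  returned as flagged `NA`, never silently 0 and never an exception.
* Top-fraction thresholding retains exactly ceiling(f N) edges; ties at
  the boundary are broken lexicographically by (tf_id, target_id) so a
  network is reproducible to the byte.
* All randomness (simulation, splits, fold schedules, initialization,
  shuffling, permutation nulls) flows from explicit integer seeds through
  R's RNG. Every pure-R stage (simulation, featurization, splitting,
  thresholding, the TSV writers) reproduces bit-exactly under a fixed
  seed. Training and scoring go through BLAS matrix products, where a
  threaded BLAS may reassociate floating-point sums between runs;
  reproducibility there is to ~1e-15 relative (exact under a
  single-threaded BLAS), which the tests assert at 1e-10.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at the
simulator defaults (400 pairs; 280/120 train/test split; ten epochs with
patience 3). The label-shuffled null uses a 720-pair simulation with a
0.3 train fraction so that the null AUROC is measured on ~500 held-out
pairs, where its binomial standard error (~0.026) makes the 0.5 ± 0.08
acceptance band a ~3-sigma check. The scan demonstration scores 10 TFs
against 150 candidates and validates the top decile against the planted
network with 10,000 permutations. These sizes are the package's own
choices for a complete, convincing desk-scale demonstration.

## Known limitations

* The simulator's single-latent-factor structure is far easier than real
  regulatory inference; reported synthetic AUROCs are near-ceiling by
  design and say nothing about performance on curated gold standards.
* Negative training pairs are uniform non-edges; true-but-unknown edges
  among them are accepted label noise, as is conventional.
* The CNN engine is CPU-only and tuned for desk-scale corpora (hundreds
  to thousands of images); genome-scale scans stream in chunks but are
  compute-bound at roughly 30 ms per pair on one core.
* Gene identifiers are matched as exact strings; alias resolution is an
  external-database concern and out of scope.
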