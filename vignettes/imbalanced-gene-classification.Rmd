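---
title: "Imbalance-aware classification of gene-expression microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware classification of gene-expression microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(geneximb)
```

## The problem

Microarray gene-expression datasets used for cancer classification combine
two pathologies. First, *class imbalance*: clinically interesting subtypes
are rare, so a training set may hold 52 samples of one leukemia subtype and
only 9 of another. A classifier trained on such data drifts toward the
majority class, and its headline accuracy hides near-total failure on the
minority. Second, the *curse of dimensionality*: thousands to tens of
thousands of gene probes against a few dozen samples, with only a small
subset of genes carrying class information.

`geneximb` implements a pipeline that attacks both at once: minority
oversampling with the SMOTE family up to a balance-to-majority target,
filter-based gene selection by chi-square and information gain with an
intersection-based combined selector, a homogeneous 1/3/5-nearest-neighbour
majority-voting ensemble (plus configurable library backends), and
evaluation harnesses that keep every fitted statistic on the training side
of each split.

## Normalization

Expression values are min–max scaled per gene, $\tilde{x} = (x - x_{\min}) /
(x_{\max} - x_{\min})$, so that each gene contributes comparably to
Euclidean neighbourhoods. Two details are deliberate:

* **Fitting scope.** By default the model is fitted on the training split
  only and applied to the test split, which can therefore fall outside
  $[0, 1]$; values are *not* clipped, since clipping would silently discard
  the information that a test sample sits outside the training range. A
  `normalize_scope = "full"` mode fits on the whole dataset for studies that
  normalized before splitting; the leakage-safe mode is the default.
* **Constant genes.** When $x_{\max} = x_{\min}$ every value maps to 0
  rather than erroring: a constant gene has zero discriminative power and
  this keeps it inert in every distance computation.

## The SMOTE family and the balance-to-majority plan

All oversamplers share one planning rule: every class's training count is
raised to the majority class's count, so a 27:11 training set receives 16
synthetic minority samples. In multiclass data each non-majority class is
oversampled one-vs-rest, with all other classes pooled as "majority"
wherever a variant needs that notion.

Plain SMOTE draws a seed sample from the class (seeds cycle through the
class in index order — a deterministic allocation, since only "random
selection" is conventionally specified), picks one of its $k$ nearest
same-class neighbours (Euclidean metric on normalized features, $k = 5$ by
default, clamped with a warning when the class is smaller than $k + 1$), and
interpolates with a gap drawn from $U(0,1)$:
$x_{\text{new}} = x_{\text{seed}} + g\,(x_{\text{nb}} - x_{\text{seed}})$.

Every synthetic sample carries a provenance record (seed index, neighbour
index, gap) from which it can be replayed *exactly*; the test suite asserts
bitwise replay for every variant. Two representational choices follow from
this:

* **Signed gaps.** SVM-guided SMOTE extrapolates away from the neighbour
  when a seed's whole-set neighbourhood is mostly same-class
  ($x_{\text{new}} = x_{\text{seed}} + g\,(x_{\text{seed}} - x_{\text{nb}})$).
  Storing the gap as $-g$ makes the single replay formula above exact for
  interpolations and extrapolations alike.
* **Duplication fallback.** A one-sample class cannot be interpolated; by
  default it is an error, and with `allow_duplication = TRUE` it degrades
  to duplication recorded as seed = neighbour, gap = 0 — still replayable.

Borderline-SMOTE first categorizes each minority sample by its $m = 10$
nearest whole-set neighbours (self excluded): with $m'$ majority
neighbours, `noise` if $m' = m$, `danger` if $m/2 \le m' < m$, `safe`
otherwise. Seeds are drawn from the danger set only; when it is empty the
class falls back to plain SMOTE with a warning. Variant B1 interpolates
toward minority neighbours with gap $U(0,1)$; variant B2 additionally
directs samples toward nearest *majority* neighbours with gap $U(0, 0.5)$,
keeping them on the minority side of the segment. How synthetic counts
divide between the two directions is not conventionally fixed; this
implementation alternates deterministically (every second sample is
majority-directed), which makes counts exact and runs reproducible.

K-means SMOTE clusters the whole training set (`n_clusters` defaults to
`min(8, n/2)`), keeps clusters whose minority fraction is at least 0.5 with
two or more class members, and apportions the class budget across eligible
clusters proportionally to a sparsity weight — the mean pairwise distance
among class members raised to `density_exponent` (default
`min(sqrt(p), 2)`) — using largest-remainder rounding so totals match the
plan exactly. Plain SMOTE then runs inside each cluster, so seed and
neighbour always share a cluster (recorded in the provenance).

None of $k$, $m$, or the k-means settings has a canonical published value
for this pipeline; the defaults above are the conventional choices from the
resampling literature and are all configurable.

## Gene selection: chi-square, information gain, and their intersection

Both filters operate on discretized expression. The default discretizer is
recursive entropy-based binary partitioning with the MDL stopping rule: a
cut is accepted only when its information gain exceeds
$(\log_2(N-1) + \Delta)/N$, with
$\Delta = \log_2(3^c - 2) - (c\,H(S) - c_1 H(S_1) - c_2 H(S_2))$. On
pure-noise genes this almost always yields no cut, so the gene collapses to
a single bin and scores zero — which is exactly what a threshold-zero
filter needs. An equal-width discretizer (10 bins by default) is available
for data where supervised cuts are undesirable or degenerate.

Scores are the familiar ones: $\chi^2 = \sum (O - E)^2 / E$ over the
bin-by-class contingency table, and $IG = H(\text{class}) -
H(\text{class} \mid \text{bin})$ in bits. Both are nonnegative, so the
"drop non-positive ranks" threshold is implemented as a strictly-positive
filter. Rankings sort by descending score with gene-id tie-breaks, making
selection deterministic. Top-$N$ selection keeps the first $N$ survivors
(all of them, with a warning, if fewer survive).

The combined selector intersects the chi-square and information-gain top-$N$
sets, keeping chi-square order. Its size can never exceed the smaller
input — the sense in which the combination is strictly more parsimonious —
and an empty intersection warns, since downstream classification needs at
least one gene.

**Stage order.** When oversampling is enabled the default order is
normalize → oversample → select → classify: selection then sees the
balanced training set, and the selected panel reflects the data the
classifier will actually train on. The reverse order is available via
`select_before_oversample = TRUE`; on imbalanced data the two orders
genuinely select different panels, and the suite asserts that.

## Classification

The package's own contribution is the homogeneous k-NN voting ensemble:
1-NN, 3-NN and 5-NN models sharing one training set and metric, combined by
majority vote. Determinism required two tie-break rules that convention
leaves open: distance ties resolve by training index order, k-NN vote ties
resolve to the nearest neighbour's class, and ensemble vote ties resolve to
the smallest-k (most local) model. Infeasible k values on tiny training
folds are dropped with a warning.

The MLP sizing rule sets the hidden layer to the rounded half-up average of
input and output dimensions — `mlp_hidden_units(300, 7)` is `r
mlp_hidden_units(300, 7)`.

Other backends are configuration layers over established libraries
(`randomForest`, `e1071`, `nnet`, `rpart`, `xgboost`), shipped with the
conventional ensemble presets (100 gini trees for random forests, C = 1
one-vs-one SVMs with polynomial or RBF kernels, and so on). Two
approximations are documented rather than hidden: the `puk_approx` SVM
kernel is an RBF stand-in for the Pearson-universal kernel (which no common
R library provides), and the MLP preset's `learning_rate`/`momentum` fields
describe the reference backprop configuration but are not consumed by
`nnet`'s quasi-Newton optimizer, so only the sizing rule is operative.

## Evaluation

Per-class precision, recall and F1 are computed one-vs-rest in percent,
with a zero-denominator convention of 0 plus a warning. Averages are
**support-weighted**, not macro: under support weighting the weighted
recall is algebraically identical to the accuracy
($\sum_c \frac{n_c}{N}\frac{TP_c}{n_c} = \frac{\sum_c TP_c}{N}$), which is
also the averaging style under which published per-class tables collapse to
their accuracy column. Cross-validation is stratified; the headline number
is the pooled (micro) confusion matrix across folds, with per-fold metrics
attached. Within each fold the *entire* pipeline — normalization,
oversampling, selection, backend — is refitted on the training split only,
and the per-fold provenance records make the no-leakage property assertable
rather than assumed: no synthetic sample's seed or neighbour may be a
test-fold sample, ever.

Effect comparison against a no-oversampling baseline labels each metric
delta positive, negative or negligible with a threshold of 0.5 percentage
points — an artifact convention, since no canonical threshold exists.
An optional PCA front end (50 components by default) is fitted on the
training split and applied to both splits.

## The synthetic-data generator

The generator emulates the *statistical shape* of benchmark microarray
datasets: grouped classes with arbitrary imbalance (down to 52:9),
nonnegative intensities, and a small planted panel of informative genes.
Informative gene $g$ in class $c$ (0-based class index) is drawn from
$\mathcal{N}(\mu_0 + c\,\delta\sigma,\ \sigma)$ with base intensity
$\mu_0 = 10$, noise $\sigma = 1$ and effect size $\delta$ in noise-sd
units; noise genes share $\mathcal{N}(\mu_0, \sigma)$, and everything is
clamped at zero. This is the simplest structure under which filter-selection
recovery is provable; a log-normal option adds skew for realism. Identical
spec + seed is bit-identical.

`make_reference_fixtures()` reproduces the class counts and fixed
train/test splits of four published benchmark shapes (a 5-class curated
leukemia collection of 64 samples, a 7-class leukemia-subtype set of 327, a
binary ALL/AML set of 72, and a binary colon-tumor set of 62) with a reduced
default of 500 genes so the full test suite stays fast.

What the generator does **not** emulate: probe-level artifacts, batch
effects, heavy-tailed intensity distributions, gene–gene correlation, or
platform differences. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — exact counts, exact provenance, recovery of
planted signal, absence of leakage — not clinical performance on real
microarrays, which depends on structure the generator deliberately omits.

## Validation choices and problem sizes

The test suite runs entirely on generated data at sizes chosen to finish in
about a minute: benchmark-shaped fixtures at 60–500 genes, parameter
recovery on 1,000 genes × 61 samples (52:9, effect 3, 20 informative genes,
20 seeds), and the end-to-end run on the 5-class 64-sample shape at 500
genes. Two choices in the null (effect-size 0) end-to-end arm deserve
explanation:

* MDL discretization on pure noise correctly returns empty selections,
  which aborts the pipeline by design (an empty gene panel is an error, not
  a silent fallback). The null arm therefore uses equal-width
  discretization with a wider top-N so the pipeline runs end to end.
* A SMOTE-balanced classifier on pure noise spreads its predictions across
  classes, so its accuracy falls *below* the majority-class rate rather
  than matching it. "No signal" is therefore tested one-sidedly: the
  pipeline must not be significantly *better* than majority-class guessing
  (binomial test, pooled over 20 seeds, α = 0.01).

## Known limitations

* Neighbour searches build full pairwise distance matrices — fine for
  microarray-scale cohorts (tens to hundreds of samples), not for
  thousands.
* The PUK-kernel SVM and backprop-MLP configurations are approximated as
  described above.
* Discretization is univariate; genes informative only in combination score
  zero on both filters and cannot be recovered by this family of selectors.
* Undersampling, hybrid resampling and Tomek-link cleaning are out of
  scope, as are probe annotation and platform-specific preprocessing.
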