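---
title: "Moment-based encoding and ensemble classification of driver genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based encoding and ensemble classification of driver genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seqmoments classifies DNA gene sequences into two groups -- disease
*driver* genes (positive class) versus *passenger* genes (negative
class) -- from sequence alone. A variable-length sequence is mapped to a
fixed 522-coefficient vector that summarises both composition and the
relative positioning of bases; tree ensembles are then trained and
validated on those vectors. This vignette explains the encoding, the
classifier configurations, the validation protocols, the synthetic
benchmark generator, and the numerical and design choices behind each.

## The encoding

A sequence $S = \rho_1\rho_2\ldots\rho_n$, $\rho_i \in \{A, C, G, T\}$,
is coded numerically as $A{=}1, C{=}2, G{=}3, T{=}4$. The codes are
nonzero so that the padding introduced next is distinguishable from
every base; beyond that the mapping is an arbitrary labelling, and
every model downstream is tree-based, hence invariant to its monotone
relabellings. The coded sequence is reshaped row-major into the
smallest square matrix that holds it, $K = \lceil\sqrt{n}\rceil$, with
$K^2 - n$ trailing zeros.

Three families of **statistical moments**, all orders $a+b \le 3$ (ten
index pairs per family), summarise each matrix view $M$:

* raw moments $D_{ab} = \sum_{p}\sum_{q} p^a q^b M_{pq}$ over 1-based
  row/column indices;
* central moments $V_{ab} = \sum_{g}\sum_{h}(g-\bar x)^a(h-\bar y)^b
  M_{gh}$ about the centroid $(\bar x, \bar y) = (D_{10}/D_{00},
  D_{01}/D_{00})$, taken as $(0,0)$ when $D_{00}=0$;
* Hahn moments $H_{pq} = \sum_i\sum_j \tilde h_p(i)\,\tilde h_q(j)\,
  M_{ij}$, projections onto orthonormal discrete Hahn polynomials on
  $x = 0..K-1$.

The Hahn family is used with its parameters fixed at $a = b = 0$, where
it coincides with the discrete Chebyshev (Gram) polynomials. That
choice makes the weight uniform, so orthonormality is plain Euclidean
and the polynomials are generated by the standard three-term
recurrence, each order normalised numerically to unit norm. Keeping
*all* $K^2$ orders makes the transform exactly invertible (the tests
verify reconstruction to $10^{-6}$ per cell for $K \le 12$); the
encoder keeps the ten low orders as a fixed-size, information-dense
summary. Orders up to 3 require $K \ge 4$, which is why the encoder
requires sequences of length $\ge 10$.

**Position relative incidence matrices (PRIM)** capture where k-mers
occur relative to one another. For k-mer types $i, j$ (overlapping
occurrences, 1-based start positions, lexicographic order $A<C<G<T$):

$$\mathrm{PRIM}_k(i,j) \;=\; \sum_{p \,\in\, \mathrm{occ}(j)}
  \bigl(p - \mathrm{first}(i)\bigr),$$

zero when either type is absent. The rule is order-sensitive
(the matrix is not symmetric) and cells can be negative when $j$ occurs
before the first occurrence of $i$; it costs $O(n)$ per $k$ after
indexing, since it reduces to $\mathrm{sumpos}(j) - \mathrm{count}(j)
\cdot \mathrm{first}(i)$. Several position-incidence accumulation rules
appear in the pseudo-K-tuple literature and the element-wise definition
is genuinely open; this one was chosen as the simplest rule that is
position-sensitive in both arguments and reproduces the intended
$4^k \times 4^k$ shapes ($16$, $256$ and $4096$ cells for $k = 1, 2,
3$). RPRIM is the PRIM of the *string-reversed* sequence -- strict
reversal, no complementation anywhere in the package.

**Positional accumulation vectors**: the frequency vector counts each
of the $4^k$ k-mers (counts sum to $n-k+1$); AAPIV sums the 1-based
start positions of each k-mer's occurrences (entries sum to
$(n-k+1)(n-k+2)/2$, every position counted once); RAAPIV is the AAPIV
of the reversed sequence. All three are computed at $k = 1, 2, 3$.

The **522-coefficient layout** (tag `moments522/v1`, itemised by
`feature_layout()`): 30 moments (10 raw + 10 central + 10 Hahn) for
each of nine matrix views -- forward sequence matrix, reversed-sequence
matrix, PRIM $k{=}1,2,3$, RPRIM $k{=}1,2,3$, and the $4\times4$
dinucleotide adjacency-count matrix -- giving 270, plus frequency,
AAPIV and RAAPIV vectors at $k = 1,2,3$ (84 each), giving 522. The ten
moment pairs per family (rather than the eight sometimes quoted) are
what "all orders up to 3" requires, and are what makes the arithmetic
close at 522. The tag travels with every feature table and fitted
model, and models refuse tables with a different tag.

## Classifiers

`default_spec()` carries the tuned configuration of each family:

| family | configuration | backend |
|---|---|---|
| `random_forest` | 50 trees, max depth 25, OOB scoring, mtry $=\sqrt p$ | ranger |
| `xgb` | 100 rounds, depth 9, seed 0 | xgboost |
| `lgbm` | leaf-wise histogram GBM, 31 leaves, 100 rounds, seed 42 | xgboost (`lossguide`) |
| `extra_trees` | 100 unlimited-depth extremely randomised trees | ranger |
| `bagging` | 10 bootstrap trees over all features (mtry $= p$) | ranger |
| `stacking` | bases xgb + RF + logistic + lgbm; logistic meta-learner | in-package |

`warm_start` and `n_jobs` are recorded in the specification for
fidelity to that tuning but are inert: the package never refits
incrementally, and training is pinned to one thread so a fixed seed
yields bit-identical models. The logistic learner (a stacking base and
the meta-model) is ridge-penalised (glmnet, $\alpha = 0$, $\lambda =
10^{-3}$): with $p = 522$ features and modest $n$ an unpenalised fit is
rank-deficient and unstable, while a small ridge keeps it deterministic
and well-posed without materially constraining it.

**Stacking** builds its meta-features leakage-free: rows are split into
5 stratified internal folds, each base learner is refit 5 times, and
the meta-feature of a row is the prediction of a base model that never
saw that row. The fold count follows the common default for stacked
generalisation; the tests probe the no-leakage property directly by
substituting label-memorising base learners and checking that the
meta-features equal out-of-fold predictions, not training labels.

## Metrics and validation protocols

With $tp, fn, tn, fp$ the confusion counts (positive class 1):
$S_n = tp/(tp{+}fn)$, $S_p = tn/(tn{+}fp)$, $Acc = (tp{+}tn)/N$, and
the Matthews correlation coefficient with the convention
$\mathrm{MCC} = 0$ when a denominator factor vanishes. Accuracy is
identically the prevalence-weighted blend of $S_n$ and $S_p$, which the
tests assert over random confusion tables. Reports print Acc/Sn/Sp as
percentages and MCC on $[-1, 1]$. ROC curves sweep every observed
score as a threshold; AUC is the trapezoid area (cross-checked against
pROC in the tests).

Three protocols are provided: **self-consistency** (train and test on
all rows -- a sanity check that the encoder and a flexible learner can
reproduce the training labels, saying nothing about generalisation);
**independent evaluation** (stratified 70/30 splits, 10 repeats by
default, mean and per-repeat metrics); and **stratified k-fold
cross-validation** (each row tested exactly once). Splits and folds
are stratified by class rather than fully random: the intended
benchmarks are near-balanced and stratification removes a variance
term without changing the estimand. One consequence: folds hold at
least one row of each class, so "leave-one-out" in the strict
single-row sense is not reachable; `k` may not exceed the smaller
class size.

## The synthetic benchmark generator

Real driver/passenger benchmarks are assembled from curated genome
databases; the generator stands in for them so that every stage of the
pipeline can be exercised, calibrated and regression-tested without
downloads. Negatives are i.i.d. uniform over $\{A,C,G,T\}$. Positives
start from the same background and receive
$\mathrm{round}\!\bigl((e-1)(L-k+1)/4^k\bigr)$ planted copies of each
signal k-mer at random positions, bringing their expected occurrence
rate to $e$ times the background's. Planting a deterministic
expected count (rather than a Poisson draw) keeps the realised
enrichment factor exact per sequence. Defaults: three 5-mers
(`GGCGG`, `ATCGT`, `CAGGA`) -- 5-mers so the signal reaches the
$k \le 3$ encoder only through constituent sub-k-mers, and GC-skewed
first so the planted composition shift resembles the GC/CpG-island
contrast real regulatory regions show; the `strong` preset uses
$e = 8$ and lengths 200--1000 nt. With `signal = "none"` ($e = 1$) the
two classes are generated identically, giving an exchangeable null.

What the generator does *not* emulate -- and therefore what passing
tests do not show about real data: codon structure, isochore/GC
heterogeneity, repeats, homology between related genes, and class
imbalance. Uniform background composition is a deliberate
simplification; the generator tests the pipeline, not biology.

A property worth knowing when interpreting results on the strong
preset: sequence length varies five-fold there, the layout's counts
and position sums scale with length, and the planted signal scales
with it too, so raw-count features carry the class signal partly
confounded with length. Self-consistency reaches 100% (deep forests
memorise), and cross-validated accuracy sits well above the null band
-- the tests assert both, plus monotonicity of cross-validated
accuracy in the enrichment factor across $1\times, 4\times, 8\times$
-- but cross-validated accuracy on this preset should not be expected
to approach the self-consistency ceiling: a length-normalised
composition would expose the signal more directly than the fixed
raw-count layout does. That is a property of the encoding, shared with
its real-data use, not a generator artefact.

## Redundancy reduction

Benchmark assembly conventionally removes near-duplicate sequences by
greedy identity clustering at a threshold (0.70 is the convention this
package mirrors). `reduce_redundancy()` implements a greedy
longest-first clusterer whose identity estimate is the fraction of
shared overlapping 5-mers relative to the 5-mer count of the shorter
sequence -- the same short-word logic the standard clustering tools use
as their filter, kept as the *definition* here for reproducibility. It
is not a re-implementation of any external tool, and makes no claim of
bit-compatibility with one.

## Numerical choices and degenerate inputs

* Centroid of an all-zero matrix: $(0,0)$, making central moments of
  the zero matrix well-defined zeros.
* Hahn basis: recurrence plus per-order numerical normalisation;
  orthonormality holds to $10^{-10}$ for every $K$ used, and the
  full-order transform reconstructs to $10^{-6}$ per cell up to
  $K = 12$ (the magnitudes in the unnormalised recurrence stay well
  inside double range for all $K \le 64$ used by the encoder).
* MCC with a zero denominator factor is 0; a protocol run whose test
  fold lacks a class reports the undefined rate as `NaN` with a
  warning rather than failing silently.
* Feature CSVs store doubles at full `write.table` precision (15
  significant digits), so a round trip is lossless well past the
  12-digit contract; the layout tag rides in a leading comment line.
* Ties in redundancy clustering (equal lengths) keep input order;
  representatives are the cluster founders (longest members).
* Decision threshold is 0.5 unless configured; scores are
  positive-class probabilities.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make every
stochastic assertion stable under its fixed seeds while keeping a full
run inside a coffee break: oracle-equivalence over 100 random
sequences of lengths 10--200; self-consistency and null calibration on
400-sequence benchmarks (200 per class); enrichment monotonicity at 80
sequences per dataset with three repeats per enrichment level. The
null-calibration band is three binomial standard errors around chance
for the number of rows actually tested.

## Known limitations

* The 522 layout is one defensible itemisation of moment blocks and
  positional vectors; alternatives exist, which is why tables and
  models carry an explicit layout tag instead of assuming one.
* The PRIM accumulation rule is one member of a family of plausible
  definitions (see above); results are internally consistent under the
  tag but not comparable across different rules.
* Raw counts confound composition with sequence length (discussed
  above).
* The greedy 5-mer clusterer approximates, not reproduces, external
  redundancy-reduction tools.
* Probability calibration of scores is not attempted; thresholds other
  than 0.5 are the caller's responsibility.
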