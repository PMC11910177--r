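# seqmoments

Sequence-based classification of disease **driver genes** (genes whose
mutations are associated with causing a disease, such as Parkinson's)
versus **passenger genes**, from DNA sequence alone.

Variable-length gene sequences cannot feed a tabular classifier
directly. seqmoments maps each sequence
`S = ρ1 ρ2 … ρn`, `ρ ∈ {A, C, G, T}`, to a fixed vector of **522
coefficients** and then trains and validates tree-ensemble classifiers
on those vectors. The encoding combines:

* **Statistical moments** (all orders `a + b ≤ 3`) of nine matrix views
  of the sequence — the numerically coded sequence reshaped row-major
  into a `⌈√n⌉ × ⌈√n⌉` square matrix (forward and reversed), position
  relative incidence matrices, and the dinucleotide adjacency matrix:
  - raw moments `D_ab = Σ_p Σ_q p^a q^b M[p,q]`,
  - central moments `V_ab = Σ_g Σ_h (g − x̄)^a (h − ȳ)^b M[g,h]` about
    the centroid `(D10/D00, D01/D00)`,
  - Hahn moments `H_pq = Σ_i Σ_j h̃_p(i) h̃_q(j) M[i,j]` on the
    orthonormal discrete Hahn (a = b = 0, i.e. discrete Chebyshev)
    polynomial basis — a transform that is exactly invertible when all
    orders are kept;
* **PRIM / RPRIM**, `4^k × 4^k` accumulators (k = 1, 2, 3) of each
  k-mer's occurrence positions relative to every k-mer's first
  occurrence, on the forward and string-reversed sequence;
* **frequency / AAPIV / RAAPIV vectors** (k = 1, 2, 3): k-mer counts
  and sums of occurrence start positions, forward and reversed.

Classifier configurations ship for random forest (50 trees, depth 25),
XGB, a leaf-wise histogram GBM, extremely randomised trees, bagging,
and a stacking ensemble with leakage-free out-of-fold meta-features.
Validation protocols: self-consistency, repeated stratified 70/30
splits, and stratified k-fold cross-validation, reporting accuracy,
sensitivity, specificity, MCC (`(tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))`)
and ROC/AUC. A synthetic two-class generator with controllable k-mer
enrichment provides download-free, fully reproducible benchmarks.

See `vignettes/moment-encoding.Rmd` for the full account of the model,
its parameters and its design choices.

## Worked example

```r
library(seqmoments)

ds  <- generate_dataset(synthetic_preset("strong", n_per_class = 60, seed = 7))
ds
#> Labeled DNA dataset: 120 sequences ( 60 positive / 60 negative )
#> Length range: 212 - 998 nt

tab <- encode_dataset(ds)
tab
#> Feature table: 120 sequences x 522 coefficients (layout  moments522/v1 )
#> Labels: 60 positive / 60 negative

fit <- fit_classifier("random_forest", tab)
#> trained random_forest on 120 rows (60 positive / 60 negative) in 0.87 s

kfold_eval(tab, "random_forest", k = 5, seed = 1)
#> Evaluation report -- kfold ( stratified 5-fold cross-validation )
#> Classifier: random_forest ; seed: 1 ; 5 run(s)
#> Mean metrics: Acc 72.50%  Sn 73.33%  Sp 71.67%  MCC 0.4596
#> Mean AUC: 0.7986
```

The report reads: averaged over five stratified folds, 72.5% of
held-out sequences were classified correctly, 73.3% of true driver
(positive) sequences were recovered, 71.7% of passenger (negative)
sequences were correctly rejected, and the Matthews correlation (a
balanced summary on [-1, 1], 0 = chance) was 0.46 — a real but partial
recovery of the planted 8× k-mer enrichment at this small benchmark
size, far above the chance level that the same pipeline reports on
signal-free data. Self-consistency (training-set) evaluation of the
same configuration scores 100% across the board, as a deep forest
should on separable data. `feature_layout()` documents every
coefficient:

```r
head(feature_layout(), 3)
#>   index name                            block                              description
#> 1     1 f001 moments: forward sequence matrix raw moment 00 of forward sequence matrix
#> 2     2 f002 moments: forward sequence matrix raw moment 01 of forward sequence matrix
#> 3     3 f003 moments: forward sequence matrix raw moment 10 of forward sequence matrix
```

## Command line

A thin launcher over the same functions lives at `inst/cli/seqmoments`:

```sh
Rscript inst/cli/seqmoments synth  --out-dir data --n-per-class 200 --seed 1
Rscript inst/cli/seqmoments encode --positives data/positives.fa \
    --negatives data/negatives.fa --out data/features.csv
Rscript inst/cli/seqmoments eval   --features data/features.csv \
    --family random_forest --protocol kfold --k 10 --out-prefix data/cv
Rscript inst/cli/seqmoments train  --features data/features.csv \
    --family random_forest --model-out data/rf.model
Rscript inst/cli/seqmoments predict --model data/rf.model \
    --fasta data/positives.fa --out data/scores.csv
```

`encode` accepts `--cluster-threshold 0.70` to apply greedy 5-mer
identity clustering before labelling, mirroring conventional benchmark
preprocessing.

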