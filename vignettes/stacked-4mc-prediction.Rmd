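---
title: "Predicting 4mC sites with stacked ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 4mC sites with stacked ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stack4mC)
```

## The problem

N4-methylcytosine (4mC) is a DNA modification in which the N4 position of
a cytosine carries a methyl group. It is common in prokaryotes, where it
participates in restriction–modification systems, and has been mapped in
eukaryotic genomes (including mouse) by SMRT sequencing. Experimental
detection is expensive, so sequence-based classifiers are used to triage
candidate sites: given a fixed-length DNA window centred on a cytosine,
predict whether that cytosine is methylated.

`stack4mC` implements the full pipeline for this task: window I/O and
validation, two feature encodings, a two-stage stacked ensemble of four
heterogeneous base classifiers under a logistic metaclassifier, the
standard four-indicator evaluation harness with ROC/AUC, and a synthetic
benchmark generator so that every stage is testable without external
data.

## Windows

The unit of prediction is a 41-nt window with the candidate cytosine at
position 21 (1-based, inclusive coordinates; the centre of an odd window
of length $L$ is $(L+1)/2$). Both validation rules — length 41, centre C
— are on by default in `read_windows()` and can be disabled to use the
encoders at other window lengths. Two label conventions are supported,
matching how such benchmarks ship: one FASTA file per class, or a
two-column `id<TAB>label` sidecar.

Ambiguity codes (N and friends) are outside the model's alphabet. The
reader offers two policies: `strict` (abort naming the first offending
record — the default, because silent data loss is worse than a loud
failure) and `drop` (exclude and log, for scanning real contigs).
Input sequences are taken as given; no reverse-complement
canonicalization is applied, since the strand convention of public 4mC
benchmarks is not stated and silently collapsing strands could destroy
signal.

## Feature encodings

**K-mer composition.** For window $D$ of length $L$ and k-mer $X$,

$$f(X) = \frac{F(X)}{L - k + 1},$$

where $F(X)$ counts *overlapping* occurrences. Each k-block is a
probability vector (nonnegative, sums to 1). With $k = 1..5$ the window
maps to $4 + 16 + 64 + 256 + 1024 = 1364$ features. Columns are ordered
lexicographically with $A < C < G < T$ inside each block, blocks in
ascending $k$; the order is emitted as a column manifest with every
feature matrix so fitted models are portable. No pseudocounts and no
scaling are applied.

**EIIP.** Each nucleotide is replaced by its electron-ion interaction
pseudopotential (A 0.1260, C 0.1340, G 0.0806, T 0.1335), giving a
41-dimensional positional encoding. EIIP is a pure per-position lookup:
permuting two input positions permutes exactly the two corresponding
outputs.

**Multifeature.** The concatenation [k-mer 1..5 | EIIP], 1405 dimensions
at $L = 41$, k-mer first. The two blocks are deliberately complementary:
k-mer features are position-free composition, EIIP features are
composition-free position. No standardization is applied between blocks;
the k-mer entries live in $[0, 1]$ and EIIP entries in $[0.08, 0.14]$,
and the learners that are scale-sensitive (the SVM) receive the raw
scales by default, with an opt-in `scale` hyperparameter recorded in the
learner's configuration.

## Base learners

Four heterogeneous classifiers sit behind one contract: `fit(X, y,
seed)` then `score(X')` returning a positive-class probability per row.
Determinism given the seed is part of the contract and is tested.

* **Discrete Bayes network** (`bayesnet`). Features are discretized with
  the Fayyad–Irani recursive entropy procedure: the candidate cut
  minimizing the class-weighted entropy is accepted only if its
  information gain exceeds the MDL coding cost, recursively. Features
  with no accepted cut collapse to one bin and drop out. On the
  discretized features the default structure is naive Bayes — which is
  also the structure a max-one-parent search started from naive Bayes
  selects — with conditional probability tables smoothed by 0.5.
  `structure = "tan"` additionally gives each feature at most one
  feature parent along the maximum spanning tree of pairwise conditional
  mutual information given the class; this search is quadratic in the
  feature count and intended for modest dimensionalities, not the full
  1405-feature encoding.
* **Multinomial naive Bayes** (`nb_multinomial`), Laplace smoothing
  $\alpha = 1$, treating the nonnegative feature vector as event
  weights. Implemented in-package because no installed R package
  provides the multinomial variant.
* **RBF SVM** (`svm`), through e1071's libsvm binding with C = 1 and
  $\gamma = 1/\text{dim}$, the library defaults. Probabilities are a
  Platt-style sigmoid fitted by logistic regression of the training
  labels on the training decision values. libsvm's built-in probability
  machinery shuffles with the C `rand()` stream and is therefore not
  reproducible call-to-call; the in-sample sigmoid is deterministic,
  which the scoring contract requires. The cost of this choice is
  slightly optimistic calibration (the sigmoid sees resubstitution
  decision values); rank-based quantities (AUC) are unaffected.
* **Voted perceptron** (`voted_perceptron`), implemented from the
  Freund–Schapire description: a linear (degree-1 polynomial) kernel
  with an implicit bias feature, one epoch by default, visiting the data
  once in a seed-shuffled order. Every intermediate weight vector is
  kept with its survival count; an instance's score is the
  survival-weighted fraction of vectors voting positive — an affine,
  monotone squashing of the vote margin into $[0, 1]$.

The **metaclassifier** is logistic regression via `stats::glm`. A weakly
ridge-penalized fit was considered; the reference implementations of
this metaclassifier use a ridge of $10^{-8}$, which is numerically the
unpenalized estimate, so plain `glm` is used rather than a bespoke
penalized IRLS. On the 4-column meta feature space separation is rare;
if it occurs the fitted scores saturate but remain valid probabilities.

Learners register by name in a registry (`register_learner()`), which is
the extension point for third-party classifiers: anything honouring the
fit/score contract can serve as a base or meta learner in a config.

## The stacking procedure

Stage 1 splits the training set into $k = 10$ stratified folds
(per-class cyclic dealing, so fold sizes differ by at most one and class
counts per fold are within one of proportional; 1492 instances give fold
sizes 149–150). For each base learner and each fold $j$, a model is
fitted on the other nine folds; its scores on fold $j$ are stacked
vertically into that learner's out-of-fold column of the meta matrix
$A$ ($n \times 4$), and its scores on the test set are averaged over the
ten fold models into the corresponding column of $B$ ($m \times 4$).
Stage 2 fits the logistic metaclassifier on $(A, y)$ and applies it to
$B$.

Two design choices deserve emphasis:

* **Meta features are probabilities, not hard labels.** Averaging ten
  hard 0/1 votes would quantize the test-side features to elevenths and
  discard ranking information; probability averaging keeps $B$ on the
  same scale as $A$.
* **Deployment reuses the fold models.** `predict_stack()` scores new
  windows exactly the way $B$ was built — ten fold models per base,
  averaged — rather than refitting each base on the full training set.
  The metaclassifier was calibrated against fold-model outputs, and
  refit bases would shift that calibration.

The no-leakage property — instance $i$'s meta feature comes from a model
whose training indices exclude $i$ — is machine-checked in the tests by
instrumenting every fold model with its training index set, and
separately witnessed by a memorizing probe learner whose out-of-fold
column collapses to 0.5 (it has never seen the rows it scores).

## Evaluation

From confusion counts (ties at the 0.5 threshold go positive,
everywhere):

$$\mathrm{ACC} = \frac{TP + TN}{n},\quad
\mathrm{Sn} = \frac{TP}{TP + FN},\quad
\mathrm{Sp} = \frac{TN}{TN + FP},$$

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP\!+\!FP)(TP\!+\!FN)(TN\!+\!FP)(TN\!+\!FN)}},$$

with MCC defined as 0 when any denominator factor vanishes (the standard
convention; the counts are promoted to doubles because the denominator
overflows 32-bit integers already near $n \approx 500$). The ROC curve
sweeps the distinct score values as thresholds; tied scores form a
single step, so trapezoid integration equals the Mann–Whitney
probability that a random positive outscores a random negative with
ties counted ½. Both routes are kept honest in the tests against a
pairwise-enumeration oracle and against pROC.

Two protocols are provided. `crossvalidate()` runs an *outer*
stratified k-fold loop in which the entire stacking procedure — inner
folds included — is re-run per outer fold, and pools the concatenated
out-of-fold predictions into one set of metrics (pooling, rather than
averaging per-fold metrics, is robust to fold-size imbalance; per-fold
reports are also returned). `independent_test()` fits on one labelled
set and evaluates on a disjoint one, warning if the sets share ids or
sequences.

## The synthetic benchmark generator

`generate_windows()` draws windows i.i.d. from a background composition
(uniform by default) and forces the centre to C. Positives can carry
two kinds of planted signal, chosen to exercise the two encoders
independently: a positional consensus motif (corrupted per position
with probability `noise`; a corrupted position is redrawn uniformly, so
a motif position matches its consensus with probability
$1 - \frac{3}{4}\,\text{noise}$), and a dinucleotide log-enrichment map
applied through a first-order Markov chain.

`generate_benchmark_shaped()` emulates the shape of the published mouse
4mC benchmark — 746+746 training and 160+160 test windows, 41 nt,
centre C, balanced classes — with the default signal: motif `GTACGTCA`
at offset 8, noise 0.2. That default was set analytically, before any
pipeline runs: with match probability 0.85 per motif position, the
likelihood-ratio test on the 8 motif positions achieves roughly 0.989
sensitivity and 0.973 specificity, i.e. Bayes accuracy ≈ 0.98, a
deliberately learnable but imperfect problem.

What the generator does *not* emulate: real 4mC context (no biological
motif grammar), genomic base composition and autocorrelation, CD-HIT
style redundancy structure, and class imbalance. Passing the synthetic
recovery tests therefore demonstrates that the pipeline's machinery
recovers planted signal without leakage — it says nothing about
accuracy on real genomes, for which users must supply the real
benchmark FASTA files.

## Problem sizes used by the test suite

The suite checks the heavy properties at sizes chosen to keep a full
run comfortably interactive on one core: the planted-signal recovery
and label-permutation checks run once each at the full benchmark shape
(1492/320); the 10-seed stacked-versus-best-base AUC comparison runs at
200+200 training and 80+80 test windows with 5 inner folds; the
generator's signal-strength monotonicity sweep uses 60+60/30+30 windows
over three noise levels and 10 seeds with a two-learner stack. Measured
under these conditions, the full four-base stack reaches independent
test accuracy ≈ 0.91 on the default synthetic benchmark, the
label-permuted control falls to ≈ 0.5, and the mean stacked AUC sits
within 0.02 of the mean best single base (0.961 vs 0.978).

## Known limitations

* The Weka hyperparameters behind the published benchmark figures are
  unstated upstream; this package fixes documented defaults instead, so
  agreement with the published numbers on the real benchmark is a soft
  expectation, not a contract.
* The TAN structure search is quadratic in features and impractical at
  the full 1405-dimensional encoding; it exists for low-dimensional use
  and for verifying that the naive structure is the degenerate case.
* SVM probability calibration is in-sample (see above); downstream,
  the metaclassifier partially re-calibrates, and out-of-fold meta
  features are unaffected by construction.
* The generator's uniform background makes k-mer features
  near-exchangeable; compositional learners look weaker there than on
  genomic backgrounds with skewed composition.
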