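---
title: "Covariance encoding and SVM classification of recombination hot/cold spots"
author: "daccspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance encoding and SVM classification of recombination hot/cold spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daccspot)
```

## The problem

Meiotic recombination is unevenly distributed along a genome: some regions
recombine at markedly elevated frequency (hotspots) and others hardly at all
(coldspots). Given only the DNA sequence of a candidate region, `daccspot`
predicts which of the two classes it belongs to. The package targets the
standard yeast benchmark setting — two labeled sets of genomic regions, 490
hotspots and 591 coldspots — but works on any two-class collection of DNA
sequences of varying length.

The scientific difficulty is that sequences differ in length, while most
classifiers need a fixed-length numeric representation. Composition features
(k-mer counts) solve that but discard *sequence order*. The encoding used
here keeps order information by measuring how physicochemical properties of
the DNA double helix co-vary along the molecule.

## The DACC encoding

Every adjacent base pair step (dinucleotide) of a sequence has measurable
physical properties: helical twist, roll, tilt, slide, rise, stacking
energy, melting enthalpy and entropy, and their flexibility counterparts.
The package ships a table of 15 such properties over the 10 strand-symmetric
dinucleotide classes (a step and its reverse complement are the same
physical object, so AA/TT, AC/GT, ... share values). `property_table()`
returns it; custom 15-property tables can be loaded from CSV.

For a sequence $R_1 R_2 \ldots R_L$ and property $\mu$, the profile
$P_\mu(i)$, $i = 1..L-1$, is the property value of the dinucleotide at
positions $i..i{+}1$. Two families of covariance features summarise the
profile at positional offsets ("lags"):

auto covariance (DAC), one property against itself,

$$\mathrm{DAC}(\mu, lag) = \frac{1}{L-1-lag} \sum_{i=1}^{L-1-lag}
  \bigl(P_\mu(i) - \bar P_\mu\bigr)\bigl(P_\mu(i+lag) - \bar P_\mu\bigr),$$

and cross covariance (DCC), property $\mu_1$ at position $i$ against
$\mu_2$ at $i + lag$,

$$\mathrm{DCC}(\mu_1, \mu_2, lag) = \frac{1}{L-1-lag} \sum_{i=1}^{L-1-lag}
  \bigl(P_{\mu_1}(i) - \bar P_{\mu_1}\bigr)\bigl(P_{\mu_2}(i+lag) - \bar P_{\mu_2}\bigr),$$

where $\bar P_\mu$ is the profile mean over all $L-1$ positions. The DACC
vector concatenates both blocks for every lag $1..LAG$: with $N$ properties
it has $N \cdot LAG + N(N-1) \cdot LAG$ entries — $90 + 1260 = 1350$ at the
default $N = 15$, $LAG = 6$. Cross pairs are ordered ($\mu_1$ at the earlier
position), so both $(\mu_1,\mu_2)$ and $(\mu_2,\mu_1)$ appear. The feature
length no longer depends on $L$, which is the point: arbitrary-length
sequences map into one fixed feature space that retains order information up
to offset $LAG$.

Numerical conventions worth stating explicitly:

* **Denominator.** Each covariance divides by the number of summands,
  $L - 1 - lag$, the canonical form in the auto-cross covariance family of
  encoders. The minimum accepted length is $L \ge LAG + 2$ so every lag has
  at least one summand; a single-summand covariance is simply the product of
  the two deviations.
* **Profile mean.** Centering uses the mean over all $L-1$ positions, not
  only the positions entering a given lag's sum.
* **Feature order.** DAC iterates property (table order) outer, lag inner;
  DCC iterates ordered property pairs outer, lag inner. Feature names are
  `DAC(mu,lag)` and `DCC(mu1,mu2,lag)`, so any entry is recoverable from its
  name.
* **Input validation.** Case-insensitive A/C/G/T only; ambiguity codes are
  rejected with the offending 1-based position, or skipped per record when
  `skip_invalid = TRUE` in `encode_batch()`. Positions in all messages and
  outputs are 1-based.
* **Property scaling.** The default encodes with the raw published property
  values, whose scales differ by orders of magnitude (flexibility-rise spans
  ~14–25, flexibility-roll ~0.03–0.06), so large-scale properties dominate
  kernel distances and weight magnitudes. `standardize = TRUE` z-scores
  each property row across the 10 classes first — a common variant in this
  encoder family — but raw is the default because the published operating
  point is defined on the raw table.

## PCA reduction

With 1350 correlated features and roughly a thousand training sequences,
dimension reduction both speeds up training and removes noise directions.
`fit_pca()` centers the training matrix, eigendecomposes its sample
covariance (divisor $N-1$), and keeps the smallest number $l$ of leading
components whose cumulative eigenvalue share reaches the threshold $w$
(default $0.99$). Two conventions make fits reproducible: eigenvalues are
reported in non-increasing order, and each retained eigenvector is flipped
so its largest-magnitude coordinate is positive (the eigenvector sign is
otherwise arbitrary). The covariance — not correlation — matrix is used:
reduction is applied to the feature blocks as encoded, without rescaling.

Inside every evaluation protocol the PCA is refit on the training fold only;
the held-out sequences are projected with the training-fold model. A
`fast_pca` shortcut that reuses one full-data projection across jackknife
folds exists solely to probe how much that leakage matters, and always
warns.

## The classifier

A C-support-vector classifier with RBF kernel
$k(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$ separates the classes;
defaults are $C = 2^3$ and $\gamma = 2^{-3}$, and `grid_search_svm()`
optimises both on a log2 grid ($\log_2 C \in [-5, 15]$,
$\log_2 \gamma \in [-15, 3]$, step 2) by stratified cross-validated
accuracy, breaking ties toward the smaller $C$ then smaller $\gamma$. The
quadratic program is solved by kernlab's C-SVC at tolerance $10^{-4}$; the
solution of this convex problem is solver-independent up to that tolerance,
and the test suite cross-checks decision values against an independent
LIBSVM fit. Hotspot is the positive class everywhere: decision values are
sign-normalised so positive means hotspot, and an exactly-zero decision
resolves to hotspot.

### Interpretation: the discriminative weight vector

For a model with signed dual coefficients $A_i = \alpha_i y_i$ (zero for
non-support vectors) trained on feature matrix $M$, the per-feature score

$$W_j = \sum_i A_i \, M_{ij}$$

ranks features by discriminative power (by $|W_j|$, descending; the sign is
retained in the output). This is a deliberate *pseudo-linear* readout of an
RBF model — it is the primal weight vector the same dual coefficients would
induce under a linear kernel, not the gradient of the RBF decision function
— and it is used only for ranking and visualisation, never for prediction.
Because $W_j$ scales with the feature's raw magnitude, rankings on raw
(unstandardised) encodings favour large-scale properties; that caveat is
inherent to the formula.

## Evaluation protocols

`jackknife_eval()` implements leave-one-out: every sequence is held out
once, and PCA (when enabled) and the SVM are refit on the remaining
sequences. Encoding is sequence-local — each feature vector depends only on
its own sequence — so it is computed once up front without leakage; the
engine additionally asserts that no held-out row reaches a fold's fit.
`kfold_eval()` does the same with stratified folds from a seeded shuffle
($k = n$ is accepted and reduces to the jackknife). Metrics are sensitivity,
specificity, accuracy and the Matthews correlation coefficient, recomputed
from stored confusion counts; an MCC denominator with a zero factor is
defined as 0. `lag_sweep()` re-encodes at each candidate maximum lag and
reports the k-fold accuracy at a fixed seed, mirroring how the operating
point $LAG = 6$ is chosen in practice.

One performance note: when reduction is disabled, the fold engine
precomputes the full RBF kernel matrix once and each fold solves its SVM on
the training submatrix. Kernel entries depend only on pairs of encoded
sequences — no training statistics enter them — so this is exact and
leakage-free, and it makes the full 1081-sequence jackknife run in a few
minutes on one CPU. With reduction enabled each fold needs its own
eigendecomposition, which is why the package's own large-scale jackknife
demonstrations use the raw-feature pipeline and exercise the PCA variant
through 5-fold cross-validation at the same benchmark shape; jackknifing
the PCA pipeline is supported and simply costs one PCA refit per sequence.

## The synthetic generator

Real hotspot/coldspot benchmarks are external data; the package instead
ships a generator whose classes differ *exactly in the quantity the encoder
measures*. Negatives are i.i.d. uniform A/C/G/T. Positives are drawn from a
lag-factorised copy chain: nucleotide $j$ copies nucleotide $j - \ell$ with
probability $p$ (the `effect_size`) and is uniform otherwise, where $\ell$
is the planted lag. This is a first-order Markov chain within each residue
class modulo $\ell$; successive dinucleotides at offset $\ell$ then agree
with probability $\approx p^2$, inflating the lag-$\ell$ autocovariance of
every dinucleotide property while leaving single-nucleotide composition
uniform and injecting nothing alignment-like (no motifs, no positional
anchors). `signal_property` designates which feature the tests track —
by default flexibility-rise (`F-rise`), the property with the largest raw
profile variance, since $|W|$-rankings on raw-scale features favour exactly
those. At `effect_size = 0` the two classes are generated identically and
are exchangeable by construction.

Defaults were fixed once, by a calibration run before any test expectations
were written: class sizes 490/591 for the benchmark preset (100/100
otherwise), lengths uniform on 200–600 nt (typical of the intergenic
regions in recombination benchmarks), planted lag 3 (inside the default
$LAG = 6$ window), and `effect_size = 0.3`. At that effect the planted
feature's class means differ by roughly 35 pooled standard errors, the
no-reduction jackknife accuracy is about 0.98 at $n = 200$, and the planted
feature ranks first among 1350 by $|W|$ — a clearly detectable but not
saturated signal (0.10 gives ~0.79 accuracy, 0.45 gives ~0.995).

What passing on synthetic data does and does not show: the generator
emulates the *statistical mechanism* the encoder targets (property
autocovariance differences at a planted lag) under uniform base
composition. It does not emulate yeast genomic composition, GC-content
landscapes, repeat structure, or any actual recombination biology, so
synthetic accuracies say nothing about accuracy on real benchmarks — they
verify that the pipeline detects what it claims to detect, with a null
control at chance level.

## Problem sizes used by the shipped checks

The packaged test-and-demonstration runs use: the full 1081-sequence
benchmark-shaped jackknife (no reduction) plus a 5-fold evaluation of the
$w = 0.99$ PCA pipeline at the same shape; a 200-sequence null-effect
jackknife; encoder-versus-brute-force comparison on 100 random sequences of
lengths 10–500; and a 50-seed exchangeability check at small $n$. These
sizes keep the whole suite within a few minutes on a single CPU while
exercising every code path at the benchmark's scale.

## Known limitations

* The printed performance of the original yeast benchmark (jackknife
  accuracies near 82–83%, MCC near 0.65, a 173-dimension reduced space)
  can only be reproduced with that benchmark's FASTA, which is not
  redistributed here; with a user-supplied copy, `evaluate --protocol
  jackknife` on defaults is the corresponding run. Whether its PCA was
  refit per fold is not documented; this package refits per fold, which can
  shift the retained dimension and metrics slightly.
* The discriminative weight vector is a pseudo-linear interpretation of a
  nonlinear model (see above) and depends on feature scaling.
* Only A/C/G/T sequences are supported; ambiguity codes must be cleaned or
  skipped, and RNA is out of scope.
* With $p < 1$ sequence-length variation (200–600 nt) the per-sequence
  covariance estimates are noisy at large lags; very short sequences
  ($L < LAG + 2$) are rejected rather than padded.
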