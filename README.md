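# daccspot

Classification of meiotic recombination **hotspots** versus **coldspots**
from DNA sequence alone, for genomicists working with two-class collections
of genomic regions (the canonical setting is the yeast benchmark of 490
hotspots and 591 coldspots).

## The method

Variable-length sequences are mapped into a fixed feature space by
**dinucleotide-based auto-cross covariance (DACC)**. Each overlapping
dinucleotide of a sequence $R_1 \ldots R_L$ is assigned the values of 15
physicochemical properties (twist, roll, tilt, slide, shift, rise, their
flexibility counterparts, stacking energy, enthalpy, entropy) over the 10
strand-symmetric dinucleotide classes. For property $\mu$ with profile
$P_\mu(i)$ and mean $\bar P_\mu$:

$$\mathrm{DAC}(\mu, lag) = \frac{1}{L-1-lag}\sum_{i=1}^{L-1-lag}
 (P_\mu(i) - \bar P_\mu)(P_\mu(i{+}lag) - \bar P_\mu)$$

$$\mathrm{DCC}(\mu_1, \mu_2, lag) = \frac{1}{L-1-lag}\sum_{i=1}^{L-1-lag}
 (P_{\mu_1}(i) - \bar P_{\mu_1})(P_{\mu_2}(i{+}lag) - \bar P_{\mu_2})$$

Concatenated over lags $1..LAG$ this gives $N \cdot LAG$ auto- and
$N(N-1) \cdot LAG$ cross-covariance features — **90 + 1260 = 1350** at the
default $N = 15$, $LAG = 6$. The vector is optionally reduced by PCA,
keeping the smallest number of leading components reaching a cumulative
eigenvalue share $w$ (default 0.99), and classified by an RBF-kernel SVM
(defaults $C = 2^3$, $\gamma = 2^{-3}$). Evaluation uses the jackknife
(leave-one-out) or stratified k-fold protocols with per-fold refitting and
reports Se, Sp, Acc and Matthews correlation. A discriminative weight
vector $W_j = \sum_i \alpha_i y_i M_{ij}$ ranks features by their
contribution, for interpretation.

A built-in generator produces two-class synthetic sequence sets whose
classes differ exactly in property autocovariance at a planted lag, so the
whole pipeline is testable end to end without external data. See the
methods vignette (`vignettes/dacc-hotspot-classification.Rmd`) for the
model details, numerical conventions and design choices.

## Worked example

```r
library(daccspot)

sim   <- simulate_recspots(synthetic_spec(n_pos = 50, n_neg = 50, seed = 42))
feats <- encode_batch(sim$sequences, sim$labels)
feats
#> DACC feature matrix: 100 sequences x 1350 features
#>   labels: 50 hot / 50 cold

jackknife_eval(feats, pipeline_config(reduce = FALSE))
#> Evaluation: jackknife on 100 samples
#>   TP 48  FP 0  TN 50  FN 2
#>   Se 0.9600  Sp 1.0000  Acc 0.9800  Mcc 0.9608

model <- train_classifier(feats)
w     <- discriminative_weights(model, feats)
head(w[order(w$rank), c("feature", "mu1", "mu2", "lag", "weight", "rank")], 5)
#>                feature     mu1     mu2 lag    weight rank
#>          DAC(F-rise,3)  F-rise    <NA>   3  89.94557    1
#>  DCC(F-slide,F-rise,3) F-slide  F-rise   3  58.10103    2
#>  DCC(F-rise,F-slide,3)  F-rise F-slide   3  57.30255    3
#>     DCC(F-rise,roll,3)  F-rise    roll   3 -43.37363    4
#>     DCC(roll,F-rise,3)    roll  F-rise   3 -42.39606    5
```

Each held-out sequence was predicted by a model refit without it; the
98% accuracy and MCC 0.96 reflect the planted covariance signal at lag 3,
and the weight ranking recovers exactly the planted feature
`DAC(F-rise,3)` and its cross-covariance partners.

With your own data, supply FASTA + a two-column label TSV (or separate
hotspot/coldspot FASTA files); the original yeast benchmark is evaluated
with the defaults (`pipeline_config()`, jackknife).

## Command line

A thin wrapper script is shipped at `inst/cli/daccspot`:

```sh
daccspot simulate --n-pos 100 --n-neg 100 --seed 1 \
    --out-fasta sim.fasta --out-labels sim.tsv
daccspot encode   --fasta sim.fasta --labels sim.tsv --lag 6 --out features.csv
daccspot evaluate --fasta sim.fasta --labels sim.tsv --protocol jackknife \
    --no-pca --out report.json
daccspot interpret --fasta sim.fasta --labels sim.tsv --out weights.csv
```

Subcommands: `simulate`, `encode`, `reduce`, `train`, `predict`,
`evaluate`, `sweep-lag`, `interpret`. Options can also come from a YAML
file (`--config run.yaml`); explicit flags win. Every report embeds the
fully resolved configuration and seeds.

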