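# hotspotEL

Sequence-based classification of meiotic **recombination hotspots and
coldspots** by an ensemble of three support vector machines.

Recombination clusters in narrow genomic regions: hotspots recombine far
more often than coldspots. `hotspotEL` predicts, from a region's DNA
sequence alone, which class it belongs to. It is aimed at genomicists who
have candidate regions in FASTA and want a reproducible, fully offline
classifier plus its evaluation machinery.

## Method

Three fixed-length encodings of a sequence `D = R1 R2 ... RL` feed three
RBF-kernel SVMs whose Platt-scaled class probabilities are averaged:

1. **Kmer** — overlapping k-mer frequencies `count/(L-k+1)`,
   lexicographic order, `4^k` components (k = 6 → 4096). Local
   composition.
2. **DACC** — dinucleotide auto/cross covariance over 15 physicochemical
   properties (z-scored per property across the 16 dinucleotides):

       DAC(μ, g) = Σ_{i=1}^{L-g-1} (P_μ(i) − P̄_μ)(P_μ(i+g) − P̄_μ) / (L−g−1)

   and analogously DCC for ordered property pairs (μ1 ≠ μ2), distances
   g = 1..lag. With 15 properties and lag = 6: 90 + 1260 = 1350
   components. Global sequence order.
3. **PseDNC** — the 16 dinucleotide frequencies plus λ correlation tiers
   θ_j (mean squared property difference between dinucleotides j apart),
   weighted by w: `16 + λ` components (λ = 7, w = 0.3 → 23), summing to 1.

The ensemble averages the members' class probabilities,
`R_j = (1/3) Σ_i P_i(S, L_j)`, and predicts the class with the larger
mean (ties → hotspot). Per-encoder SVM hyperparameters are fixed:
kmer `C = 2^7, γ = 2`; dacc `C = 2^3, γ = 2^-3`; psednc
`C = 2^13, γ = 2^3`.

Evaluation is leave-one-out (jackknife) by default, reporting
sensitivity (hotspot recall), specificity (coldspot recall), accuracy,
Matthews correlation coefficient, and ROC/AUC.

## Worked example

```r
library(hotspotEL)

# synthetic two-class data: hot sequences carry encoder-specific signals
train <- complementarySignalDataset(30, 30, lengthRange = c(150, 250), seed = 11)
model <- trainEnsemble(train, seed = 1)

newSeqs <- complementarySignalDataset(3, 3, lengthRange = c(150, 250), seed = 99)
predict(model, newSeqs)
#>         id        R1        R2    label
#> 1  hot_001 0.6002619 0.3997381  hotspot
#> 2  hot_002 0.6164504 0.3835496  hotspot
#> 3  hot_003 0.3993232 0.6006768 coldspot
#> 4 cold_001 0.3254077 0.6745923 coldspot
#> 5 cold_002 0.4403947 0.5596053 coldspot
#> 6 cold_003 0.3700433 0.6299567 coldspot
```

`R1` is the ensemble's mean hotspot probability, `R2 = 1 − R1` the
coldspot probability; the label is the larger of the two. (Five of these
six held-out sequences are called correctly; `hot_003` carries the
hardest, longest-range signal.)

Metric arithmetic from a confusion table (hotspot = positive):

```r
round(classMetrics(374, 116, 69, 522), 3)
#>     Se     Sp    Acc    MCC
#> 76.327 88.325 82.886  0.654
```

Real labeled data go through the same path: read sequences with
`readFastaDna()`, build a `HotspotDataset`, then `trainEnsemble()` /
`jackknifeEvaluate()`. A command-line front end is installed at
`exec/hotspotEL` (subcommands `simulate`, `encode`, `train`, `predict`,
`evaluate`, `tune`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/hotspotEL", package="hotspotEL"))')" \
    encode --method psednc --lamada 7 --weight 0.3 input.fasta -o features.svm
```

writes sparse SVM-light feature files (`label index:value ...`).

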