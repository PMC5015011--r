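---
title: "Ensemble SVM classification of recombination hotspots: methods and design"
author: "hotspotEL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SVM classification of recombination hotspots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotEL)
```

## The problem and the model

Meiotic recombination is unevenly distributed along a genome: hotspots
recombine far more often than coldspots. Given only the DNA sequence of a
candidate region, `hotspotEL` predicts which of the two classes it belongs
to. The predictor is an ensemble of three radial-basis-function SVMs, each
trained on a different fixed-length encoding of the same sequence:

* **k-mer frequencies** — the occurrence frequency of each overlapping
  k-mer, `count / (L - k + 1)`, in lexicographic order (`4^k` components
  summing to 1). Pure local composition; blind to where along the region a
  word occurs.
* **Dinucleotide auto-cross covariance (DACC)** — each of the 15
  physicochemical properties turns the sequence into a numeric series over
  its `L - 1` overlapping dinucleotides. For property $\mu$ and distance
  $g \in 1..lag$ the auto-covariance is
  $$\mathrm{DAC}(\mu, g) = \frac{1}{L-g-1}\sum_{i=1}^{L-g-1}
    \bigl(P_\mu(i) - \bar P_\mu\bigr)\bigl(P_\mu(i+g) - \bar P_\mu\bigr),$$
  with $\bar P_\mu$ the per-sequence mean over all dinucleotide positions;
  the cross-covariance DCC does the same for ordered pairs of distinct
  properties. The vector is the DAC block (property-major, then lag)
  followed by the DCC block (ordered pairs in row-major order over the
  property grid, skipping the diagonal), giving
  $p \cdot lag + p(p-1) \cdot lag = 1350$ components for $p = 15$,
  $lag = 6$. This is global sequence-order information.
* **Pseudo dinucleotide composition (PseDNC)** — the 16 dinucleotide
  frequencies $f_k = \mathrm{count}_k/(L-1)$ augmented with $\lambda$
  correlation tiers
  $$\theta_j = \frac{1}{L-1-j}\sum_{i=1}^{L-1-j}\Theta(i, i+j), \qquad
    \Theta(i,j) = \frac{1}{p}\sum_{\mu=1}^{p}
    \bigl(P_\mu(i) - P_\mu(j)\bigr)^2,$$
  combined as $d_k = f_k / (1 + w\sum_j\theta_j)$ for $k \le 16$ and
  $d_{16+j} = w\,\theta_j / (1 + w\sum\theta)$, a probability vector of
  $16 + \lambda$ components mixing composition with tiered order
  correlations.

Each base SVM outputs Platt-calibrated class probabilities; the ensemble
averages them,
$R_j = \tfrac13\sum_{i=1}^{3} P_i(S, L_j)$, and predicts the class with
the larger mean. The three encodings capture complementary views
(local composition / global covariance structure / a mixture), which is
why averaging helps when no single view carries all of the signal.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `k` | k-mer length | 6 |
| `lag` | maximum dinucleotide distance in DAC/DCC | 6 |
| `lambda` | number of PseDNC correlation tiers | 7 |
| `w` | PseDNC weight of the tiers vs composition, in [0, 1] | 0.3 |
| `C`, `gamma` (kmer) | SVM regularization / RBF width | $2^7$, $2$ |
| `C`, `gamma` (dacc) | | $2^3$, $2^{-3}$ |
| `C`, `gamma` (psednc) | | $2^{13}$, $2^3$ |

These are the fixed working points of the method; `gridSearch()` can
re-tune `C`/`gamma` on new data, but evaluation never re-tunes inside
folds — each fold uses the same fixed values, so the reported jackknife
numbers measure the stated configuration, not a tuning procedure.

The property table ships 15 dinucleotide properties (six flexibility
parameters, six equilibrium structure parameters — angles in degrees,
translations in Å — and three nearest-neighbour thermodynamic parameters).
Published tables list 10 strand-symmetric values per property; a
dinucleotide and its reverse complement are the same base-pair step, so
each class value is copied to both members to cover all 16 dinucleotides.

### Property standardization

The covariance and $\Theta$ sums mix properties whose native scales span
three orders of magnitude (rise ≈ 21 Å-units vs shift ≈ 0.01). Left raw,
two or three properties would dominate every sum, so each property is
z-scored across its 16 dinucleotide values before use — population
(divide-by-16) standard deviation, following the convention of standard
pseudo-component feature generators. Raw values are retained and every
encoder accepts `normalized = FALSE` for users who want native units.

## Numerical and convention choices

These conventions are frozen so that feature files are reproducible
across runs and versions:

* Kmer denominator is the window count `L - k + 1`; PseDNC's $f_k$
  denominator is `L - 1`, which makes $\sum f = 1$ and the PseDNC vector
  sum exactly 1.
* DAC/DCC use denominator `L - lag - 1` with exactly `L - lag - 1`
  summands; sequences must satisfy `L >= lag + 2` (and `L >= lambda + 2`
  for PseDNC) so every sum has at least one term. Violations are errors
  naming the offending sequence, never silent zero-padding.
* DCC includes both ordered pairs $(\mu_1,\mu_2)$ and $(\mu_2,\mu_1)$.
  The SVM is indifferent to any fixed feature order; the order matters
  only for file-level reproducibility and is documented above.
* $\Theta$ averages over all 15 properties.
* An exact fused tie $R_1 = R_2$ (within 1e-12) is called a hotspot; the
  max rule alone is silent on ties.
* MCC is defined as 0 (with a warning) when a confusion-table marginal is
  zero.
* ROC curves sweep the distinct score values with ties grouped; AUC uses
  the trapezoidal rule, which the tests verify equals the pairwise
  concordance statistic.
* Ambiguous bases (N etc.) are rejected by default; `strip-ambiguous` is
  opt-in because silently editing a sequence changes every downstream
  feature. Case is normalized unconditionally; no reverse-complement or
  strand handling is applied anywhere.
* Probability calibration (Platt scaling inside LIBSVM) involves an
  internal cross-validation; its fold assignment is seeded through R's
  RNG, making training bit-reproducible for a fixed seed.
* No length ceiling is imposed on input sequences.

## Evaluation protocol

`jackknifeEvaluate()` is the reference protocol: every sequence is
predicted by an ensemble trained on all the others. Feature encodings are
per-sequence quantities, so they are computed once and cached across
folds; only the SVMs are refitted, which keeps 60-fold leave-one-out runs
in the tens of seconds. Sensitivity is hotspot recall and specificity is
coldspot recall, both reported as percentages to two decimals, MCC to
three. The ensemble's ROC score is $R_1$, the mean hotspot probability; a
base predictor is scored by its own hotspot probability. A seeded
stratified k-fold mode (`kfoldEvaluate()`) is provided for comparison with
protocols that report 5-fold results.

On its original yeast benchmark of 490 hotspots and 591 coldspots this
method family reaches jackknife accuracies in the low 80s (percent) with
ensemble MCC ≈ 0.65; reproducing those measured values requires those
sequences, which are not distributed with the package. What the package
itself verifies offline is (a) exact metric arithmetic on the benchmark's
published confusion tables and (b) the behavioral properties below on
synthetic data.

## What the synthetic generator emulates — and what it does not

`simulateDataset()` draws each class from a first-order Markov chain over
A/C/G/T, the minimal model whose class differences are visible to all
three encoders. The frozen study conditions are: benchmark-sized runs use
490/591 sequences of 200–500 nt (`benchmarkMimic()`) with a moderate GC
enrichment (per-step C and G probability 0.30 vs 0.25) in the hot class;
test-scale runs use 30–100 sequences per class at 100–200 nt. Sequence
lengths are uniform over their range, and every dataset is a deterministic
function of its seed (Mersenne-Twister).

`complementarySignalDataset()` is a purpose-built regime in which fusion
provably has room to help: disjoint thirds of the hot class carry (1)
a planted composition-balanced hexamer motif `AACGTT` — a k-mer signal;
(2) a distance-6 base-copy correlation — invisible to hexamer counts
(any 6-mer window spans distances ≤ 5) but squarely inside the covariance
encoder's lag range; (3) a distance-8 copy — beyond `lag = 6` (a lag-6
dinucleotide pair spans 7 bases) yet visible to the $\lambda = 7$ PseDNC
tier. Each base predictor misses the thirds it cannot encode; the
averaged ensemble recovers them. The acceptance checks run at 100 + 100
training and 100 + 100 test sequences, and leave-one-out control runs use
60 sequences; these sizes give stable behavior while keeping a full suite
run in a couple of minutes.

None of this simulates real recombination biology: real hotspot signals
involve chromatin context, GC-biased gene conversion and motif families
that a first-order chain cannot express. Passing the synthetic tests
shows the pipeline is correct and that fusion behaves as designed — not
that any particular accuracy will transfer to a new genome.

## Known limitations

* Binary classification only; no multiclass or regression extension.
* Fusion is a plain average; weighted or learned fusion is out of scope.
* The RBF kernel and Platt calibration are the only options, matching the
  method's fixed design.
* Jackknife retrains 3 SVMs per left-out sequence; at benchmark scale
  (1081 sequences) that is thousands of SVM fits and is best run on a
  machine budget of hours, not the seconds-scale synthetic runs used in
  the tests.
* Sequences shorter than `max(k, lag + 2, lambda + 2)` (9 nt at the
  defaults) cannot be encoded by all three members and are rejected.
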