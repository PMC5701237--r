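---
title: "Methods: two-stage ensemble prediction of plant ribosomal proteins"
author: "rama package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ensemble prediction of plant ribosomal proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rama)
```

## The problem and the model

Ribosomal proteins (RPs) are abundant, short, and strongly positively
charged — a compositional signature of proteins that bind nucleic acids.
That signature is shared by histones (HPs), which is precisely why a single
binary classifier against a background proteome is not enough: a model that
separates RPs from arbitrary non-ribosomal proteins (NRPs) will happily
pass histones too. `rama` therefore classifies in a cascade:

1. **Stage 1 (RP vs NRP).** An ensemble of binary classifiers, each
   emitting a probability that the input is ribosomal, is averaged:
   \(P_1 = \tfrac{1}{n}\sum_{i=1}^{n} p_i\). If \(P_1 < T\) the sequence is
   called *non-ribosomal* and processing stops.
2. **Stage 2 (RP vs HP).** Sequences with \(P_1 \ge T\) are re-scored by a
   second ensemble trained to separate RPs from histones. If \(P_2 < T\)
   the call is *histone-like*; if \(P_2 \ge T\) the call is *ribosomal*.

The discriminant probability \(T\) defaults to 0.5 and applies to both
stages; `ensemble_config()` accepts a per-stage pair because raising the
threshold is the natural way to trade sensitivity for precision when
predictions feed expensive wet-lab validation. The boundary is inclusive by
definition: an ensemble mean exactly equal to \(T\) is a positive stage
call. Classification is monotone in \(T\) (raising it can only remove
ribosomal calls), and ribosomal calls are by construction a subset of
stage-1 positives; both properties are exercised in the test suite.

Each input sequence is represented by nine order-free physicochemical
attributes: the proportions of aromatic (F, Y, W), negatively charged
(D, E), nonpolar-aliphatic (G, A, P, V, L, I, M), polar-uncharged
(S, T, C, N, Q) and positively charged (K, H, R) residues; the mean
Kyte–Doolittle hydropathy; the mean residue mass; the mean residue volume;
and the sequence length. Because every attribute is a per-sequence summary
of residue counts, the representation is invariant under any permutation of
the sequence — sequence order carries no signal here, and order-dependent
features (pseudo-amino-acid composition, reduced alphabets) are explicitly
out of scope.

## Residue property tables and their calibration

The literature offers several conventions for hydropathy scales, amino
acid masses (free amino acid vs residue-in-chain, integer vs two-decimal)
and residue volumes. Rather than asserting one convention a priori, the
shipped table (`inst/extdata/residue_properties.tsv`) is **calibration
gated**: the test suite requires it to reproduce, to six decimal places,
all nine attribute values of a reference 62-residue ribosomal protein
whose values are frozen in the tests. The combination that satisfies the
gate is the Kyte–Doolittle hydropathy index, integer free-amino-acid
molecular masses (the common biochemistry-textbook Mr values; two-decimal
masses fail the gate by ~0.15 Da in the mean), and Zamyatnin residue
volumes. The table is plain TSV so an alternative convention can be
supplied via `residue_properties(path = ...)`; any replacement must still pass
`validate_property_table()`, which enforces the 3/2/7/5/3 group partition.

Ambiguity codes (X, B, Z, U, O by default) count toward length — the five
proportions divide by total length — but belong to no group and are
excluded from the three means, so no chemistry is invented for unknown
residues. A sequence consisting only of ambiguity codes has no defined
mean attributes and is an error. The proportion-sum-to-one invariant is
asserted for standard-residue sequences only.

## Training-set construction

Training data for stage 1 pairs RP positives with an NRP background; for
stage 2, with histones. Two decisions matter:

* **Annotation hygiene.** `filter_uncharacterized()` removes records whose
  annotation is empty or matches a blocklist (defaults: *unknown*,
  *uncharacterized*, *hypothetical*, *unnamed*; configurable). Class
  labels are caller-supplied — the package deliberately does not screen
  annotation text to decide what is an RP, so the method is not tied to
  any particular (and possibly retired) database release.
* **3:1 negative subsampling.** Whole-proteome backgrounds are extremely
  imbalanced. `assemble_dataset()` reduces the NRP pool to exactly
  `ceiling(3 × n_positives)` instances by seeded sampling *with
  replacement* (a without-replacement switch exists). The 3:1 ratio is
  enforced exactly and reproducibly: the same pools and seed yield a
  byte-identical dataset. RP-vs-HP sets are kept whole — histone sets are
  small and near-balanced already.

## Attribute evaluation

`rank_attributes()` scores each attribute by information gain,
\(IG = H(\text{class}) - H(\text{class}\mid\text{attribute})\), with
entropies in bits and the conditional term the bin-size-weighted mean
class entropy over a discretized attribute. The default discretizer is
Fayyad–Irani MDL-based supervised discretization, implemented in the
package: recursive binary splitting at class-boundary midpoints, a split
being accepted only when its gain beats the minimum-description-length
penalty. An attribute on which no split is accepted collapses to one bin
and scores exactly zero — matching the behaviour of the common toolkit
default that produces hard zeros in attribute rankings. Equal-frequency
binning (10 bins) is available as an alternative; with a quantile-based
discretizer IG is invariant under strictly monotone transforms of the
attribute, which the tests verify.

Ranks are made deterministic by breaking IG ties on the attribute name
(ascending). Zero-IG attributes are reported, never pruned: with only nine
attributes there is no dimensionality pressure, and attributes that are
individually uninformative can still contribute jointly.
`class_conditional_summaries()` exports per-class kernel-density (or
histogram) tables on a shared grid for plotting; classes with fewer than
two instances are omitted with a warning rather than silently densified.

## Model families and their defaults

`train_model()` wraps seven probabilistic binary classifiers behind one
interface: random forest, multilayer perceptron, naive Bayes, LogitBoost,
an information-splitting recursive-partitioning tree, and linear and RBF
support-vector machines. Implementation notes:

* Hyperparameters are frozen in `default_hyperparameters()` (forest: 200
  trees, mtry 3; perceptron: one hidden layer of 5 units, weight decay
  0.1, 300 epochs, features standardized internally; LogitBoost: 50
  stump iterations; tree: information split, minsplit 10; SVMs: cost 1,
  RBF gamma 1/9) so results do not drift with backing-library defaults.
* The SVM variants emit probabilities through the backing library's
  built-in Platt-style calibration; trees and forests emit vote or leaf
  proportions; the perceptron uses a softmax output layer.
* The tree family is a CART-style implementation with the information
  (entropy) splitting criterion — the closest available relative of C4.5;
  it is not claimed to reproduce C4.5's pruning behaviour.
* Every fit is seeded; identical `(dataset, algorithm, hyperparameters,
  seed)` give identical probabilities, and `save_model()`/`load_model()`
  round-trip predictions exactly. Model archives carry a training-set
  hash so train/serve skew is detectable.

`select_best()` picks by Matthews correlation coefficient (MCC), the
balanced criterion that is hard to inflate on 3:1-imbalanced data; ties
fall back to F-measure, then to the algorithm id, so selection is a
deterministic function of its input.

## Evaluation schemes

`compute_metrics()` applies the six standard formulas literally
(precision, accuracy, sensitivity, specificity, F-measure, MCC). A metric
whose denominator is zero is `NA`, never a silent zero. Three validation
schemes are provided:

* **k-fold cross-validation** (`kfold_cv()`): stratified, seeded folds;
  held-out confusion counts are *pooled* over folds and metrics computed
  once. Macro-averaged per-fold metrics are reported separately — pooling
  is the contract, macro-averaging is informational, and the two are
  never substituted for each other. Stratification requires every class
  to have at least `k` members when `k < n`; `k = n` is the leave-one-out
  partition, for which stratification is vacuous.
* **Jackknife** (`jackknife()`): an explicit leave-one-out loop with the
  same model seed each round. Its pooled counts coincide exactly with
  `kfold_cv(k = n)` under the same seed policy; the suite checks the two
  independent code paths against each other.
* **Inter-species tests** (`interspecies_test()`, `interspecies_sweep()`):
  train on one species, test on another, with same-species evaluation
  refused unless explicitly overridden. The sweep over six species yields
  the full 30-pair report per task.

## The synthetic benchmark: what it emulates and what it does not

Real multi-species training data lives in external proteome databases;
the package instead ships a seeded generator (`generate_proteome()`,
`default_benchmark()`) so every layer — feature extraction, IG ranking,
training, validation, the full cascade — is testable offline. Each class
is a composition-plus-length model: a probability vector over the five
residue groups (mass uniform within a group), a per-sequence Dirichlet
draw around that vector (within-class dispersion), a multinomial residue
draw, and a log-normal length. The frozen defaults are:

| class | aromatic | neg. | nonpolar | polar | pos. | median length | sdlog | dispersion |
|-------|---------:|-----:|---------:|------:|-----:|--------------:|------:|-----------:|
| RP    | .06 | .08 | .33  | .23  | .30  | 160 | .28 | 55  |
| HP    | .01 | .06 | .24  | .42  | .27  | 95  | .18 | 150 |
| NRP   | .09 | .13 | .36  | .285 | .135 | 480 | .45 | 35  |

The construction encodes the intended biology: RPs short and
positive-charge-rich; histones equally charged but shorter, aromatic-poor
and small-residue-shifted (so stage 1 cannot separate them and stage 2 is
genuinely exercised); NRPs a long, acidic, high-dispersion background.
The within-class Dirichlet dispersion is a deliberate addition: with
multinomial noise alone the classes would be nearly separable and every
evaluation would saturate at 1.0, which makes tests uninformative. The
NRP vector was chosen to partially offset the volume/mass/hydropathy
shifts that a positive-charge gap mechanically induces, so that
positive-charge proportion and length — not their correlated shadows —
dominate the information-gain ranking, as they should for this problem.
These parameters were fixed once, before the test expectations were
frozen, and are not tuned per run.

`default_benchmark()` builds six synthetic species (small species-level
Dirichlet jitter, concentration 1000) with 48 RP / 160 NRP / 30 HP
sequences each, assembles both training tasks per species, and everything
downstream — registry training, leave-one-species-out cascade evaluation
(`pipeline_loso_eval()`), the 30-pair sweeps — runs from it. These sizes
were chosen so the complete benchmark-plus-pipeline round trip takes a
few seconds and the whole suite minutes, while class counts stay large
enough for stable stratified folds.

What the generator does **not** emulate: homology and phylogenetic
structure (synthetic species are i.i.d. jitters, not a tree), real
annotation text beyond filter-trigger keywords, real length and
composition marginals (real proteomes are heavier-tailed), and any
sequence-order signal. Passing the benchmark therefore demonstrates that
the pipeline machinery is correct and that the cascade recovers a planted
compositional signal under the held-out-species protocol; it does not
certify performance on real proteomes, where class geometry is less
Gaussian and label noise exists.

## Numerical choices and degenerate inputs

* Attribute values are carried at full double precision; TSV output
  formats to six decimals (the precision at which such values are
  conventionally reported); the TSV round-trip is tested at that
  precision.
* Entropy uses the \(0\log 0 = 0\) convention; information gain is
  clamped at zero against floating-point cancellation.
* The cascade boundary is `>=` at both stages; `rank_candidates()` orders
  ribosomal calls by the *minimum* of the two stage probabilities (a
  conservative "weakest link" score; the product is available), with ties
  broken by record id.
* Parse errors name the record and the 1-based offending position; a
  single trailing `*` is stripped, an internal `*` is an error.
* Empty record collections produce empty feature tables with full
  headers, and an empty ribosomal ranking is a valid (empty) result.

## Known limitations

The tree family approximates C4.5 with CART-plus-information-splitting;
and classical toolkit default hyperparameters are matched in spirit,
not bit-for-bit.
The MCC achieved on the synthetic benchmark is higher than one should
expect on real proteomes, because the generator's classes are cleaner
than biology. The package predicts from composition only; proteins whose
ribosomal identity rests on order-dependent motifs are invisible to it.
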