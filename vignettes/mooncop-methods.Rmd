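---
title: "mooncop: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mooncop: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mooncop)
```

`mooncop` addresses a recurring situation in protein function
prediction: a small curated set of positives (moonlighting proteins,
confirmed experimentally), a set of negatives that is itself the product
of a computational pipeline, and the need to (a) compare many sequence
descriptors and classifier families fairly and (b) find out which
individual proteins are dragging performance down — because a "negative"
that every model insists is positive may simply be mislabeled. This
vignette records how each part works, which knobs matter, and where the
design was genuinely open.

## 1. Sequence descriptors

All descriptors operate on the canonical 20-letter alphabet
`ACDEFGHIKLMNPQRSTVWY` in alphabetical order; `sanitize_sequence()`
normalizes inputs first (default policy `map_x`: B→N, Z→Q, U→C, O→K,
J→L, X→A; `strict` and `drop` are available for auditing). Each
descriptor is a pure function of one sequence with a fixed, documented
feature order, and `extract_features()` refuses to emit a row for any
sequence that violates a precondition — silent padding would corrupt the
cross-validation downstream.

Key formulas (with `L` the sequence length):

* **Compositions.** `aac` is residue frequency; `aak_part_composition`
  splits the sequence into `k` contiguous near-equal parts (the first
  `L mod k` parts take one extra residue — a deterministic,
  order-preserving convention chosen because any rule satisfying the
  near-equal constraint is admissible) and concatenates part
  compositions; `saac`/`sgaac` use the first `nt = 5`, the last
  `ct = 5`, and the middle residues. `kmer_composition` and `cks_pair`
  count overlapping windows: for the k-spaced pair descriptor, position
  `i` contributes the ordered pair `(s[i], s[i+k+1])`, normalized by
  `L − k − 1`. Every composition block is non-negative and sums to 1.
* **Grouped variants** map residues to an 8-class physicochemical
  alphabet first (aliphatic GAVLI, hydroxyl ST, sulfur CM, aromatic FWY,
  basic HKR, acidic DE, amide NQ, proline P). The class count 8 is fixed
  by the published grouped vector lengths (24 = 3·8, 64 = 8², 512 = 8³);
  the exact membership is our choice of a standard chemistry-based
  partition and affects values, never lengths.
* **DDE.** For each ordered dipeptide, the observed fraction
  `Dc = N/(L−1)` is standardized against the codon-derived theoretical
  mean `Tm = (C_i/61)(C_j/61)` and variance `Tv = Tm(1−Tm)/(L−1)`:
  `DDE = (Dc − Tm)/√Tv`. The grouped variant sums member codon counts.
* **CTD.** Seven three-class physicochemical partitions. Composition is
  the class fraction; transition counts unordered adjacent class pairs
  over `L − 1`; distribution reports, per class, the sequence positions
  (percent of `L`) of the 1st, 25%, 50%, 75% and 100% occurrences, with
  occurrence index `max(1, round(q·n_c))` under **half-up rounding**
  (so the 25% occurrence among 10 hits is the 3rd, not the 2nd). A class
  absent from the sequence reports five zeros.
* **Sequence order.** `socnumber` computes
  `τ_d = Σ_i d(s_i, s_{i+d})²` for lags 1..30 over two residue distance
  matrices; `qsorder` jointly normalizes residue counts and coupling
  numbers by `Z = Σf + w·Στ` with `nlag = 5`, `w = 0.1` (both lag
  defaults are forced by the published lengths 60 and 50). The Grantham
  matrix is recomputed from Grantham's composition/polarity/volume
  formula; the second matrix is a **synthetic stand-in** for the
  Schneider–Wrede physicochemical distance, built as the Euclidean
  distance over standardized hydropathy, hydrophilicity and
  side-chain-mass scales (the original values are not redistributable
  here). It satisfies the same contract — zero diagonal, non-negative,
  finite — and all package guarantees are about formula semantics and
  lengths, not numeric identity with any other implementation.
* **Reduced k-tuple engine.** Cluster tables are data, not code
  (`inst/extdata/reduced_alphabets.tsv`), keyed by a *declared* group
  count `g`, so artificial tables may declare groups they never populate;
  length is `g^k` (16 = 4², 256 = 16², 625 = 25² with the declared-25
  identity table).
* **Autocorrelation engine.** Normalized Moreau–Broto, Moran and Geary
  statistics over property-encoded sequences, property scales
  standardized to mean 0, sd 1 across the 20 residues. The default
  bundle of 8 scales with 19 lags and all 3 kinds gives length
  3·8·19 = 456; a homopolymer has zero sequence variance and returns
  zeros for the variance-normalized kinds by convention.

Every counting descriptor is verified in the test suite against an
independent brute-force enumeration written directly from the
definitions, on random sequences, to 1e-12.

## 2. Evaluation protocol

`make_split()` reserves a class-stratified 20% holdout
(`round(0.2·n)`, half away from zero — 70 of 351). `make_fold_plan()`
builds `R` independent stratified K-fold partitions (default 100 × 10);
within each repeat every protein is in the validation fold exactly once
and fold sizes differ by at most one. The plan is a plain tibble built
**once** and passed to every `run_cv()` call being compared;
`fold_plan_checksum()` is recorded in every benchmark cell so a report
can prove all cells shared folds. Stratification is our choice (the
protocol's randomness is otherwise unconstrained): with a 136-protein
minority class, unstratified folds would occasionally starve a fold of
negatives.

Eight classifier families run behind one fit/predict interface with the
benchmark hyperparameters: SVM (RBF, C = 1), KNN (k = 5, Euclidean),
Gaussian NB, decision tree (Gini, depth ≤ 3, min split 5), random forest
(50 trees), MLP, AdaBoost (200 stumps), ridge logistic regression
(λ = 1/n, the L2 strength corresponding to C = 1). Notes on the ones we
author or adapt:

* **Gaussian NB** is implemented in-package (vectorized, with a variance
  floor of `1e-9 ×` the largest feature variance) so that
  constant-within-fold features cannot produce degenerate densities; the
  test suite cross-checks it against `e1071::naiveBayes` on clean data.
* **AdaBoost** is AdaBoost.M1 over depth-1 `rpart` stumps with the
  logistic calibration `P = 1/(1 + e^{−2F})` of the additive margin.
* **MLP** uses a single hidden layer of 20 units (`nnet`, max 150
  iterations). A two-layer (20, 3) topology is common in this
  application; single-layer is the deliberate simplification here and is
  reported as such — the family's role in the protocol (a nonlinear,
  scale-sensitive learner) is unchanged.
* Feature standardization (z-score, fitted on the training folds only)
  is on by default for SVM, KNN, MLP and LR, off for tree/ensemble/NB
  families; the flag is recorded in the config.

Per repeat, confusion counts are pooled over the K validation folds and
converted to accuracy, precision, recall, F-measure, MCC (Matthews
correlation) and rank-based AUC; the reported metric set is the mean
over repeats. Pooling-before-averaging is the default because per-fold
metrics on ~28-protein folds are noisy and undefined in corner cases;
the per-repeat table is returned (`tidy()`) so the alternative can be
computed. Zero-denominator conventions: precision/recall are 0 when
their denominator is 0, F is 0 when both are, MCC is 0 when any factor
of its denominator is 0. AUC is the Mann–Whitney pairwise-ordering
statistic with ties counted half.

All randomness derives from one master seed through a documented counter
scheme (`seed + 7919·offset mod 2³¹−1`): split, fold plan, and each
(repeat, fold) model fit draw distinct derived seeds, so any run is
reproducible from the seed alone.

## 3. Candidate outlier proteins

Across R repeats each protein collects R validation verdicts.
`tally_misclassifications()` counts the wrong ones (erroring if any
protein has ≠ R log rows); `detect_cops()` thresholds the tally. The
default rule is **inclusive** (`misses ≥ 90` of 100) with a strict
(`> 90`) mode also provided — both readings circulate, and rather than
guess we expose both and test the boundary at exactly 90. `cop_stats()`
reports the COP count ("frequency"), its class composition, and F.M.,
the fraction of COPs wrong in *every* repeat. `combine_cops()`
intersects (or unions) COP sets across descriptor × model runs;
intersection is the conservative default since a protein that defeats
*every* configuration is the strongest mislabel candidate.
`remove_and_reevaluate()` quantifies the damage: the same protocol run
with and without the flagged proteins.

Two open points resolved as package defaults: COP analysis runs on the
full labeled dataset (every protein then has exactly R verdicts; pass
the training subset explicitly to restrict it), and
`score_candidates()` — the mean MP-probability of an unlabeled sequence
over R refits — uses class-stratified bootstrap resampling of the
training set per repeat, because deterministic families would otherwise
make all 100 repeats identical and the average uninformative. With
`bootstrap = FALSE` the averaging identity (mean of identical repeats =
single run) is exact and tested.

## 4. Synthetic data: what it emulates and what it does not

`generate_synthetic()` draws i.i.d. residues: MP sequences from a
distribution in which 10 designated residues are enriched by `1 + δ`
(others depleted by `1 − δ`), NONMP from the complementary enrichment;
the first and last 5 residues use a stronger enrichment
(`min(1, 1.5δ)`) so split descriptors carry signal distinct from global
composition. A fraction of records per class is drawn from the
*opposite* distribution but keeps its nominal label — ground-truth
outliers, recorded in an attribute. Sequence lengths are uniform on
60–200 (minimum 31 keeps every descriptor defined, SOCNumber's 30 lags
being the binding constraint).

The generator deliberately has no positional grammar, no homology
structure, no organism composition and no length–class correlation:
it is sufficient to exercise every descriptor and the COP machinery, and
its null (δ = 0) is exactly exchangeable. Passing tests therefore
demonstrate the *machinery* — they do not certify performance on real
proteomes, where class signal is weaker, non-compositional and
confounded.

The default effect size δ = 0.2 was calibrated once, by running the
NB + SAAC protocol on a grid of δ values at the study conditions
(100 per class, 10% flipped labels, 100 × 10-fold), to give mean CV
accuracy ≈ 0.85 — the regime in which outlier detection is neither
trivial (clean proteins never flagged) nor hopeless — and then frozen.
At these conditions the flipped proteins are recovered with sensitivity
0.85–0.90 and a false-flag rate of 0.02–0.04, and their removal raises
mean CV accuracy by ≈ 0.11.

## 5. Problem sizes and runtimes

The test suite runs the full 100 × 10-fold recovery experiment at
200 proteins (≈ 15 s with the vectorized NB), the null calibration at
R = 20, and keeps the remaining property tests at 20–80 proteins and
R ≤ 25; the complete suite is under a minute on one core. These sizes
are the package's own test design: they are the smallest at which the
statistical claims (3-standard-error bands, rank tests) have power.

## 6. Known limitations

* The Schneider–Wrede-type matrix is a synthetic stand-in (see §1);
  QSOrder/SOCNumber values are therefore not numerically comparable
  with implementations bundling the original matrix, though all
  structural properties and the Grantham block are.
* "AAKpart" is implemented over the ungrouped 20-letter alphabet — its
  published length 60 = 3·20 forces that reading even though its
  long-form name says "grouped"; the grouped analogue is available via
  the 8-class variants.
* The AAutoCor parameterization (3 kinds × 8 properties × 19 lags
  = 456) is one consistent reconstruction of the published length; the
  engine accepts any property set, lag count and kind subset.
* PseKRAAC cluster tables are reasonable published-style groupings, not
  a reproduction of any specific tool's tables; the engine guarantees
  the `g^k` length contract for any complete table.
* MLP has one hidden layer (§2). AdaBoost stumps use `rpart`'s exact
  splitter, which may break ties differently from other gradient
  implementations.
* COP detection presumes the classifier is *mostly* right: at chance
  accuracy half the dataset would be flagged. The synthetic calibration
  (accuracy ≈ 0.85) reflects the regime where the method is meaningful.
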