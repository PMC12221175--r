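---
title: "Predicting protein-protein interactions from sequence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from sequence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whether two proteins physically interact is a binary question that underlies
pathway reconstruction, essential-gene screening and drug-target work.
Experimental interaction assays are slow and noisy, so sequence-based
computational screens are the standard complement: given only the two primary
sequences, estimate the probability that the pair interacts.  `ppigru`
implements a three-stage pipeline for this task: multi-descriptor sequence
encoding, supervised recurrent feature reduction, and gradient-boosted
classification.

## Stage 1: six complementary sequence encoders

Each protein is mapped to fixed-length descriptor vectors along two routes.

**Physicochemical-profile encoders** read a standardized 20 x 13 property
matrix (each residue described by 13 property components; each component
z-scored over the 20 residues, divisor $n-1$).  Writing $P_{k,i}$ for
component $k$ of the residue at position $i$ of a length-$L$ sequence:

* **PseAAC** (dimension $20+\lambda$): the 20 amino-acid frequencies plus
  $\lambda$ sequence-order factors
  $\theta_j = \frac{1}{L-j}\sum_{i=1}^{L-j}\Theta(R_i,R_{i+j})$, where
  $\Theta$ is the mean squared difference of the 13 standardized components
  of the two residues.  Composition and order terms share one denominator
  $\sum f + w\sum\theta$ so the vector sums to 1; the order weight defaults
  to the conventional $w = 0.05$ (the source publication does not print a
  value, so the package exposes it as a parameter).
* **AD** (dimension $3\cdot 13\cdot\lambda$): normalized Moreau-Broto
  $\frac{1}{L-d}\sum_i P_{k,i}P_{k,i+d}$, Moran (centred on the sequence
  mean, normalized by the population variance), and Geary (squared-difference
  form, normalized by the sample variance), for each property and each
  separation $d = 1..\lambda$.
* **AC** (dimension $13\cdot\lambda$): the lagged autocovariance
  $\frac{1}{L-d}\sum_i (P_{k,i}-\bar P_k)(P_{k,i+d}-\bar P_k)$.

**Class-alphabet encoders** first collapse the sequence onto seven residue
classes defined by dipole and side-chain volume (the conjoint-triad classes:
\{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}):

* **CT** (dimension $7^3 = 343$): counts of each ordered class triad over the
  $L-2$ sliding windows, normalized per protein by subtracting the minimum
  count and dividing by the maximum raw count.  (For real sequences with
  fewer than 343 distinct triads the minimum is 0 and the two possible
  readings of "subtract min, divide by max" coincide; the package divides by
  the raw maximum.)
* **LD** (dimension $10 \times 63 = 630$): composition, transition and
  distribution statistics in ten overlapping regions — the four quarters, the
  two halves, the central half, the first and last three quarters, and the
  central three quarters (12.5-87.5%).  Region boundaries use 1-based
  inclusive indices at `round(fraction * L)` with a minimum width of one.
  Distribution entries are the relative positions of the first, 25th-, 50th-,
  75th-percentile and last occurrence of each class (occurrence number
  $\lceil k\,n_c\rceil$), zero when the class is absent.
* **MMI** (dimension $84+28+7 = 119$): mutual information of the
  order-insensitive adjacent 3-grams and 2-grams on the class alphabet, plus
  the class frequencies.  With pooled frequencies $f(a)$, $f(a,b)$,
  $f(a,b,c)$ the chain is $I(a,b) = H(a) - H(a\mid b)$,
  $I(a,b,c) = I(a,b) - \left[H(a\mid c) - H(a\mid b,c)\right]$ with
  $H(a) = -f(a)\ln f(a)$, $H(a\mid b) = -f(a,b)\ln\frac{f(a,b)}{f(b)}$,
  $H(a\mid b,c) = -f(a,b,c)\ln\frac{f(a,b,c)}{f(b,c)}$, natural logarithms,
  and $0\ln 0 := 0$ everywhere.

A candidate pair is encoded per technique by concatenating the two member
vectors (first protein first), doubling the dimension.  At the default lags
$\lambda = 8, 7, 9$ for PseAAC/AD/AC the six pair widths are 56, 546, 234,
686, 1260 and 238.

Column orderings everywhere (alphabetical residues, property-major/lag-minor,
lexicographic class tuples) are frozen conventions chosen for
bit-reproducibility; the underlying methods do not prescribe an order.

### The packaged property table

The original 20 x 13 descriptor matrix is published only in a supplementary
table that is not redistributed here.  The package therefore ships a clearly
labelled synthetic stand-in (`extdata/property_table_synthetic.tsv`): 13 real
AAindex scales chosen to span the same four property groups (hydrophobic,
electronic, hydrogen-bond, steric; accession ids in the file header).  All
encoder machinery is table-agnostic — any 20 x 13 table in the documented
format can be loaded with `load_property_table()`, so users holding the
original values can reproduce the published descriptor exactly.

## Stage 2: supervised GRU reduction

Concatenated pair vectors are high-dimensional and partly redundant.  Each
technique's pair vector (dimension $d$) is consumed by a bidirectional gated
recurrent unit as a univariate sequence — one scalar feature per timestep —
and the final hidden states of the two directions (forward: after the last
step; backward: after the first) are concatenated as the reduced
representation.  Feeding the flat vector as a sequence is the package's
reading of the source architecture: it is the only shaping consistent with a
hidden width independent of $d$ and with the stated goal of extracting
implicit sequential structure from the descriptor layout.

The GRU width follows an explicit **dimension rule**:
$h = 2^{\lfloor\log_2 d\rfloor - 3}$, i.e. the exponent of the largest power
of two not exceeding $d$, reduced by 3.  For the paired PseAAC vector,
$d = 56 \Rightarrow h = 4$ and the bidirectional output width is 8; across
the six techniques the widths are 4, 64, 16, 64, 128, 16 and the merged
output is $2 \times 292 = 584$ wide.

Training attaches a single sigmoid unit to the concatenated hidden state and
minimises binary cross-entropy on the interaction labels for exactly 5
epochs with Adam (learning rate 0.001), under global-norm gradient clipping
at 1.  The head is then discarded: the supervision shapes the hidden states,
and the classifier consumes the states, not the sigmoid output.  Batch size
(64) and per-epoch reshuffling under the reducer seed are package
conventions (the source does not state them); initial parameters are uniform
on $\pm 1/\sqrt h$.  Arithmetic inside the reducers is single precision,
with denormals flushed to zero (gradients along a 1000-step chain decay
below float resolution; flushing is numerically inconsequential and several
times faster).  Given a seed, training is bit-reproducible on a fixed
platform.

Three ensemble strategies cover the design space studied in the source work,
all emitting a 584-wide merged representation so the comparison is
width-controlled:

* **MultiEns** (default): one GRU per technique, rule-derived widths,
  hidden states concatenated in the order PseAAC, AD, AC, CT, LD, MMI.
* **MultiSep**: the three profile blocks concatenated into one GRU of width
  84; the three class blocks into one of width 208.
* **MultiCon**: all six blocks concatenated into a single GRU of width 292.

The MultiCon/MultiSep widths are fixed constants (292; 84/208) taken from
the source comparison, not rule outputs: the rule applied to the
concatenated inputs would give 256 and 64/128 and break the width-matched
design.  Unidirectional variants (forward or backward reading) double their
width so output dimensionality stays comparable.

## Stage 3: gradient-boosted classification

The merged hidden states feed a gradient-boosted decision-tree classifier
with 500 boosting rounds and seed 1, all other parameters at the backend's
defaults.  The package's backend is xgboost, behind a two-function
`fit`/`predict` interface, so any classifier honouring that contract can be
substituted without touching the pipeline; the exact parameter set used is
recorded in the fitted object for audit.  Hard labels use the conventional
0.5 threshold (balanced training sets).

## Evaluation protocol

`run_cv()` performs stratified five-fold cross-validation (folds of equal
size within one; per-fold class counts within one of proportionality; seeded
assignment).  Reported metrics: ACC, PRE, SE, SP, F1, MCC, and the areas
under the ROC (trapezoid, tie-grouped thresholds — identical to the
Mann-Whitney rank form) and precision-recall (step summation) curves.  Any
zero-denominator ratio is reported as 0 and flagged.

Encoding is label-free and computed once.  The reducers are supervised, so
by default they are trained within each training split only and applied
frozen to the held-out split.  `paper_mode = TRUE` instead trains the
reducers once on the full pair set before cross-validation — the protocol of
the source evaluation, which leaks held-out labels into the reduction stage
and tends to score at least as high; it exists for faithfulness experiments
and is flagged accordingly.

`optimize_lag()` scans lags 1..11 (bounded by the shortest sequence length
minus one) for PseAAC/AD/AC.  Raw pair features go straight into the
classifier at this stage, without GRU reduction — the cheaper protocol, and
the package's reading of the source's lag search; the final chosen lags
default to (8, 7, 9) as configuration inputs rather than being re-derived,
because the published choices blend optima across datasets.  Ties break
toward the smaller lag (cheaper features).

## The synthetic-data generator

No interaction dataset ships with the package; `simulate_ppi_data()`
generates pair sets with controllable signal so that every stage is testable
offline.  Two 7-class composition profiles are separated by a chosen
total-variation distance (`effect`), splitting the shift across classes in
proportion to a fixed zero-sum direction that spares the rare cysteine
class.  The background profile aggregates average proteome residue
frequencies over the seven classes.  Proteins draw their class sequence
i.i.d. from their profile (residues uniform within class; lengths uniform in
the configured range, 50-300 by default, matching the curated-dataset regime
where sequences are at least 50 long).  Interacting pairs take both members
from one profile; non-interacting pairs mix profiles.  Signal is planted at
the class-composition level deliberately: all six encoders then carry some
signal, and the class-alphabet encoders the most, mirroring the ordering
observed on real data.

What the generator does *not* emulate: domain architecture, motif-level
binding determinants, phylogenetic correlation between sequences, shared
hub proteins with heterogeneous partners, and sequence-identity filtering.
Passing the pipeline's tests on this generator therefore demonstrates
mechanical and statistical correctness of the pipeline — encoders measure
what they claim, reducers preserve label-relevant structure, evaluation is
calibrated (accuracy at chance when `effect = 0`) — not biological accuracy
on real interactomes.

At `effect = 0.3`, compositional separation is strong and the pipeline
should recover the labels at high accuracy; the test suite asserts a mean
cross-validated accuracy of at least 0.90 in that regime and chance-level
accuracy in the null regime.

## Numerical and design choices

* Non-canonical residues (B, J, O, U, X, Z): rejected by default
  (`residue_policy = "strict"`); an explicit `"drop"` policy removes them
  with a warning.  Silent substitution would corrupt descriptors.
* Homopolymer-degenerate statistics: Moran, Geary and any undefined mutual
  information ratio are defined as 0 (their continuous limit), keeping all
  feature vectors finite.
* The property table must be standardized before encoding; standardizing
  twice is an error rather than a silent no-op, so pipelines cannot
  accidentally double-transform.
* Reducer determinism: initial parameters and epoch shuffles are generated
  in R from the reducer seed; the C++ kernel is purely sequential, so equal
  seeds give bit-identical results on a given platform.  Across platforms
  (different BLAS/compilers) reproducibility is statistical, not bitwise.
* Lag feasibility requires $L \ge \lambda + 1$; violations are reported with
  the offending sequence id.  External test pairs that violate the trained
  lags are skipped with a recorded count rather than aborting the whole set.

## Problem sizes used by the automated checks

The heavy end-to-end checks run the complete pipeline (six encoders, trained
bidirectional reducers, 500-round boosted classifier, stratified five-fold
CV).  The package's test suite runs them at 400 pairs for the null
calibration (per-fold reducer training, the sound default) and 500 pairs for
the signal-recovery and ensemble-versus-monolith comparison (full-set
reducer training, the source protocol, at matched seeds); these sizes keep
the whole suite at desk scale while leaving the chance band and the signal
margin statistically meaningful.  The dimension arithmetic checks are exact
at any size.

One behaviour deserves an explicit note: at these pair counts the monolithic
MultiCon reducer scores slightly *above* the MultiEns ensemble (under both
training protocols), whereas width-matched comparisons on large real
datasets favour the ensemble by a wide margin.  With only a handful of Adam
steps, all reducers are close to seeded random projections, and one 292-unit
recurrence simply preserves more of the concatenated input than six small
rule-width recurrences; the ensemble's advantage comes from per-technique
supervision, which needs substantially more data to express itself.  The
gap shrinks as the pair count grows.  The corresponding test records both
means and asserts the large-data ordering, so it documents this small-sample
inversion rather than hiding it.

## Known limitations

* The packaged property table is a stand-in; absolute agreement with results
  computed from the original descriptor values is not expected, though all
  dimension arithmetic, invariances and the pipeline's behaviour are
  table-agnostic.
* The recurrent reducers process one scalar per timestep; at the MultiCon
  input width (3020 timesteps) training is markedly slower than the
  per-technique ensemble, which is one practical argument for the ensemble
  design.
* `paper_mode` reproduces the source evaluation protocol but is statistically
  leaky; conclusions about generalization should use the default per-fold
  protocol or `cross_dataset_test()` on genuinely external pairs.
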