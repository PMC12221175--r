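# ppigru

Sequence-based prediction of protein–protein interactions (PPIs) with
multi-descriptor encoding, supervised bidirectional-GRU feature reduction,
and gradient-boosted classification.

## The problem

Deciding whether two proteins physically interact from their primary
sequences alone is a standard binary-classification task in systems biology:
experimental interaction screens are slow and noisy, and sequence is the one
universally available signal. `ppigru` is for computational biologists who
want a complete, reproducible reference pipeline for this task — from FASTA
files and labeled pair lists to cross-validated performance reports — with
every stage exposed as an ordinary R function.

## The model

A labeled pair set is processed in three stages:

1. **Encoding.** Each protein is mapped to six descriptor vectors:
   pseudo amino acid composition (PseAAC, dimension 20+λ), autocorrelation
   descriptors (normalized Moreau–Broto, Moran, Geary; 3·13·λ), and
   autocovariance (13·λ) on a standardized 20×13 physicochemical property
   matrix; conjoint triads (7³ = 343), local composition/transition/
   distribution descriptors (10×63 = 630), and multivariate mutual
   information (84+28+7 = 119) on a 7-class dipole/side-chain-volume
   alphabet. Pair vectors concatenate the two members, doubling each
   dimension (56, 546, 234, 686, 1260, 238 at the default lags λ = 8, 7, 9).

2. **Reduction.** Each pair vector of width *d* is consumed by a
   bidirectional GRU as a univariate sequence; the GRU width follows the
   dimension rule *h* = 2^(⌊log₂ d⌋ − 3) (so *d* = 56 → *h* = 4, output
   width 8). The GRUs are trained for 5 epochs with Adam (learning rate
   0.001, gradient-norm clip 1) against a discardable sigmoid head under
   binary cross-entropy; their concatenated final hidden states — 584 wide
   across the six techniques — are the reduced features. Three
   width-matched ensemble strategies are implemented: one GRU per technique
   (`multiens`, default), two group GRUs (`multisep`, widths 84/208), one
   monolithic GRU (`multicon`, width 292).

3. **Classification.** Gradient-boosted decision trees (xgboost backend,
   500 rounds, seed 1, otherwise default parameters) on the reduced
   features, behind a pluggable fit/predict interface.

Evaluation uses stratified five-fold cross-validation with ACC, PRE, SE, SP,
F1, MCC, AUC and AUPR; `optimize_lag()` scans λ = 1..11. A synthetic-data
generator (`simulate_ppi_data()`) plants tunable compositional signal —
interacting pairs share a residue-class profile, non-interacting pairs mix
two profiles separated by a chosen total-variation distance — so the whole
pipeline is testable without external downloads. See the methods vignette
(`vignettes/ppigru-methods.Rmd`) for formulas, conventions and design
decisions.

The packaged 20×13 property table is a clearly-labelled synthetic stand-in
(13 published AAindex scales spanning hydrophobic/electronic/hydrogen-bond/
steric character); any 20×13 table in the documented TSV format can be
substituted with `load_property_table()`.

## Worked example

```r
library(ppigru)

sim <- simulate_ppi_data(n_pairs = 60, length_range = c(40, 80),
                         effect = 0.4, seed = 42)
fit <- ppi_fit(sim$seqs, sim$pairs, epochs = 2, n_iterations = 100)
fit
#> Sequence-based PPI model (multiens, bidirectional GRU reducers -> xgboost)
#>   trained on 60 pairs; merged reduced width 584
#>   lags: PseAAC 8, AD 7, AC 9

predict(fit, sim$seqs, sim$pairs[1:3, ])
#>     id_a   id_b probability label
#> 1 P00005 P00021   0.9220121     1
#> 2 P00012 P00026   0.9828510     1
#> 3 P00032 P00056   0.9620799     1
```

The model object freezes the lags, property table, class map, trained
reducers and classifier; `probability` is the predicted interaction
probability for each pair (these three pairs are all true positives,
re-scored on their own training data) and `label` the 0.5-thresholded call.
Merged width 584 is the dimension arithmetic above:
2 × (4 + 64 + 16 + 64 + 128 + 16). Held-out performance on a fresh set,
with the default training settings:

```r
sim2 <- simulate_ppi_data(n_pairs = 150, length_range = c(40, 80),
                          effect = 0.5, seed = 42)
cv <- run_cv(sim2$seqs, sim2$pairs, strategy = "multiens", seed = 1)
round(cv$mean[c("ACC", "SE", "SP", "MCC", "AUC")], 3)
#>   ACC    SE    SP   MCC   AUC
#> 0.800 0.827 0.773 0.611 0.835
```

So at a planted class-composition divergence of 0.5 (total variation), the
pipeline recovers interactions at 80% cross-validated accuracy from 150
pairs; accuracy rises steeply with pair count (the test suite's
signal-recovery check reaches 93% at 500 pairs with full-set reducer
training), and sits at chance (50.3%) when the planted effect is zero.

## Command line

```sh
exec/ppigru simulate --n-pairs 200 --effect 0.3 --seed 1 --out demo
exec/ppigru cv --fasta demo.fasta --pairs demo.pairs.tsv --strategy multiens --out demo.cv.tsv
exec/ppigru train --fasta demo.fasta --pairs demo.pairs.tsv --out demo.model.rds
```

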