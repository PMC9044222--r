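---
title: "Hybrid MIC-mRMR filtering with a particle swarm wrapper: methods and design notes"
author: "mmpso authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid MIC-mRMR filtering with a particle swarm wrapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpso)
```

# The problem

Biomarker discovery from expression data is a feature-selection problem in
an extreme regime: tens of thousands of correlated gene features, a few
hundred labelled samples, and often a strong class imbalance (e.g. many
more tumor than normal biosamples). Pure filter methods are fast but blind
to feature interactions; pure wrapper methods model interactions but cannot
search a 60,000-dimensional subset lattice. This package implements the
hybrid strategy of running a cheap, association-based filter first and a
classifier-guided stochastic search second, so the expensive search only
ever sees a short list of high-value candidates.

The pipeline is:

1. **Preprocess** — drop features whose zero fraction exceeds a threshold;
   balance classes by random oversampling.
2. **Filter** — rank features by greedy minimum-redundancy
   maximum-relevance (mRMR) with the maximal information coefficient (MIC)
   as the association measure; keep the top *K* (all features when
   *p* ≤ *K*).
3. **Wrapper** — particle swarm optimization (PSO) over subsets of the
   top-*K* features, minimizing a cost that mixes k-nearest-neighbour (KNN)
   cross-validation error with a subset-size penalty.
4. **Validate** — stratified SVM cross-validation of the final subset, and
   optionally a logistic biomarker-panel score with ROC/AUC.

# Dependence measurement: MIC

For a sample of *n* points (x, y), every *i*-by-*j* axis-aligned grid
induces a 2-D histogram with an empirical mutual information. Writing
I\*(i, j) for the maximum over all such grids,

$$\mathrm{MIC}(x,y) = \max_{i \cdot j \le B(n)}
  \frac{I^*(i,j)}{\log \min(i,j)}, \qquad B(n) = \lfloor n^{0.6}\rfloor .$$

The normaliser makes every entry of the characteristic matrix lie in
[0, 1]; the budget B(n) caps grid resolution so the statistic does not
saturate on noise. Both logarithms use the same base, so the ratio is
base-invariant; reported discrete mutual informations use base 2 (bits).

## Estimator

Maximising I\* over both axes jointly is intractable, so the approx-mode
estimator pivots one axis and optimises the other:

* the pivot axis is partitioned into *q* bins;
* given that row assignment, the optimal column partition is found exactly
  by dynamic programming over *clump* boundaries (runs of consecutive
  points sharing a pivot bin — an optimal partition never cuts inside
  one), with the number of clumps capped at `clumpFactor × max columns`
  via a mass equipartition of clumps;
* both orientations are computed and merged entrywise, and entries are
  made monotone in (i, j), since a grid may leave cells empty.

For pivots with *q* ≥ 3 bins a single mass equipartition is used, which is
the classic heuristic. For *q* = 2 the package instead enumerates **every**
candidate cut (all boundaries between distinct pivot values, capped at
`clumpFactor × 2` candidates by mass equipartition). The enumeration costs
one extra cheap DP per candidate but makes every grid with
min(i, j) = 2 **exact**. Since grids with both dimensions ≥ 3 require
B(n) ≥ 9, the whole characteristic matrix is exact for n ≤ 38 at the
default exponent — which is what lets the test suite verify approx mode
against an independent exhaustive enumeration to 1e-12 at small n, rather
than only statistically. At large n the extra cost is a constant factor on
the q = 2 row of the matrix.

Numerical conventions:

* **Ties.** Points with equal values on an axis are never split by a grid
  line, in either mode; a real-valued grid line cannot separate equal
  values.
* **Degenerate budget.** MIC needs at least a 2×2 grid, i.e.
  floor(n^0.6) ≥ 4, i.e. n ≥ 11 at the default exponent. Smaller samples
  raise an error naming the minimum, rather than silently returning 0.
* **Constant inputs** return an all-zero, flagged characteristic matrix
  (independence from a constant), not an error.
* **Exact-1 caveat.** MIC(x, x) equals 1 exactly only when some admissible
  grid can split both axes into equal counts (e.g. even n for the 2×2
  grid); at odd small n the value is marginally below 1. Tests use even n
  where exact equality is asserted.
* The label axis of a feature-label MIC uses integer codes in sorted
  unique label order, so results do not depend on row order.

# Filter stage: greedy mRMR with the quotient criterion

With S the selected set, relevance and redundancy are

$$V = \frac{1}{|S|}\sum_{x_i \in S} \mathrm{assoc}(y; x_i), \qquad
  W = \frac{1}{|S|^2}\sum_{x_i, x_j \in S} \mathrm{assoc}(x_i; x_j),$$

and the quotient criterion asks for argmax V/W. The literal set-level
objective is exponential, so — as in standard mRMR practice — the package
ranks greedily: the first pick maximises label association; each later
step picks the candidate maximising

$$\frac{\mathrm{assoc}(y; c)}{\max\left(\frac{1}{|S|}\sum_{s \in S}
  \mathrm{assoc}(c; s),\ \varepsilon\right)}, \qquad \varepsilon = 10^{-12}.$$

The ε floor documents that the quotient is undefined at zero redundancy
and makes genuinely non-redundant candidates win by a large finite margin.
Ties break to the lowest feature index, so rankings are reproducible
across platforms. Both the literal set-level `redundancy()` (self-terms
included, so a singleton has W = 1 under MIC) and the incremental
candidate-vs-selected score are exposed and tested separately.

One property worth knowing: when the first-ranked feature is an *exact*
copy of the label, every remaining candidate's quotient collapses toward 1
(its label association equals its association with that copy), so a
perfect duplicate can tie rather than lose. The duplicate penalty bites
when candidates exist whose label association strictly exceeds their
redundancy with the selected set — the situation the greedy quotient is
designed for.

The `mi` measure (plug-in discrete mutual information, treating values as
categorical codes) is provided as a baseline for already-discrete data;
the pipeline default is MIC, which needs no pre-discretization.

# Wrapper stage: PSO over subsets

Particles carry continuous positions X in [0, 1]^d and velocities V in
[-vMax, vMax]^d over the d = min(K, p) candidate features:

$$V_{t+1} = \omega V_t + c_1 r_1 \circ (P_{best} - X_t)
  + c_2 r_2 \circ (G_{best} - X_t), \qquad
  X_{t+1} = X_t + V_{t+1},$$

with r1, r2 fresh uniform[0, 1] draws per dimension per update. Defaults
follow the study conditions: population 100, 50 iterations, c1 = c2 = 2,
ω = 0.9 (no schedule). A dimension belongs to the candidate subset when
its position exceeds 0.5 — a deterministic threshold decoding that stays
literal to the continuous update equations rather than switching to
sigmoid-stochastic binary PSO. The cost of a subset is

$$\mathrm{cost} = \alpha\, V_{error} + \beta\, \frac{N_{selected}}{N_{all}},
 \qquad \alpha = 0.95,\ \beta = 0.05,\ \alpha + \beta = 1,$$

where V_error is the KNN (k = 5) error estimated by stratified 5-fold
cross-validation on min-max-scaled features.

Design choices that the update equations do not pin down:

* **One fold assignment per run.** The CV folds are drawn once from the
  run's seed and reused for every cost evaluation, making fitness a pure
  function of position within a run. Re-drawing folds per evaluation
  would turn the search landscape stochastic and break the non-increasing
  global-best trace.
* **Empty subsets** get V_error = 1 (cost α) instead of special-casing
  the update rules; degenerate particles are penalised, not repaired.
* **Deterministic KNN.** Neighbour ties break to the lowest training
  index and vote ties to the lowest class code; together with the fixed
  folds this makes whole runs bit-reproducible from (seed, config, data).
  This is also why the KNN is implemented in the package (in C++) rather
  than delegated to `class::knn`, which breaks ties randomly.
* **Clamps.** Velocities clamp to ±4 and positions to [0, 1]; standard
  swarm practice, configurable.
* **Scaling.** Features are min-max scaled to [0, 1] before distances;
  a distance-based fitness needs commensurate scales, and the scaling is
  monotone so it does not interact with the filter stage.
* Fitness values are memoised per decoded subset: many positions decode
  to the same subset, and the memo preserves exactness while cutting
  evaluations severalfold.

# Preprocessing

The zero-fraction filter keeps a feature iff (#zeros)/n ≤ 0.5 by default.
The threshold is a tunable: published gene panels report only the outcome
of such filters, not the cutoff, so the audit trail records the removed
features and users can tune toward a target dimensionality. Filtering is
computed on the *original* rows and only then are classes balanced —
duplicated minority rows should not change sparsity statistics.

Random oversampling draws minority rows with replacement (seeded) until
all classes match the majority count; every added row is an exact copy.
The balanced data feed both the ranking and the wrapper, and the
validation folds are stratified on the balanced data. Caveat: duplicates
of one original row can land in different CV folds, which makes internal
error estimates optimistic relative to truly held-out data; the package
records which variant (balanced or original) produced every report, and
conclusions about generalisation should rest on external validation.

# Validation

* **SVM accuracy.** Stratified 10-fold cross-validation by default, RBF
  kernel with C = 1 and gamma = 1/d frozen in the report (no tuning inside
  the harness, so competing subsets are compared like for like); fold
  seeds are recorded so comparisons reuse identical folds.
* **Panel model.** Maximum-likelihood logistic regression (IRLS, tolerance
  1e-8, ≤ 100 iterations) of a binary label on the panel features, with
  the usual Wald table. (Quasi-)separation is flagged and the coefficients
  are still reported with a warning — on strongly separated expression
  panels this is the norm, and the panel probability remains usable as a
  score even when individual coefficients are unstable.
* **ROC/AUC.** The tie-aware rank formula (Mann-Whitney, half-credit for
  ties), which equals trapezoidal integration of the threshold-sweep
  curve; verified in tests against exhaustive pair counting and an
  independent ROC implementation.

# Synthetic data: what it does and does not emulate

The generator plants three feature blocks: informative features
(class-conditional Gaussians, adjacent class means separated by
`classSep` noise-SDs), redundant features (noisy monotone transforms of
randomly chosen informative features), and independent Gaussian noise.
Class imbalance follows a minority/majority ratio (e.g. 160/371 for the
motivating liver-cancer cohort). Everything is deterministic per seed,
and the returned index sets give exact ground truth for recall scoring.

This emulates what the method needs to be tested against — graded signal,
monotone redundancy, pure noise, imbalance — but *not* the full texture of
RNA-seq: no count-distribution shape, no gene-gene correlation beyond the
planted transforms, no batch effects. Passing tests therefore demonstrate
algorithmic correctness and recovery power under controlled conditions,
not end-to-end performance on any particular cohort.

# Problem sizes used by the test suite

The suite exercises each property at the smallest scale that makes it
meaningful: exhaustive-vs-approx MIC at n = 10–12 (where enumeration is
exact), calibration MICs at n = 1000, ranking oracles at p = 6, swarm
contracts at 30 features with populations of 30–50 and 20–30 iterations
over 5 seeds, coverage of the logistic panel over 200 simulations at
n = 500, and the end-to-end pipeline on 30-feature planted datasets. The
defaults users see (population 100, 50 iterations, K = 100) remain the
study conditions.

# Known limitations

* The quotient criterion is scale-free but, as noted, degenerates when a
  candidate is an exact function of the label; rankings below the first
  few positions on near-separable data carry little information.
* MIC is computed per pair; ranking p features to depth K costs O(K·p)
  MIC evaluations. This is multithreadable (`workers`) with bit-identical
  reduction, but for p in the tens of thousands the sparsity filter and a
  generous machine are assumed.
* Oversampling before cross-validation inflates internal accuracy
  estimates (duplicate straddling); see above.
* The PSO is the plain global-best variant: no inertia schedules,
  multi-swarm topologies, or mutation operators.
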