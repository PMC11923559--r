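---
title: "Connectome-based predictive modeling in cpmr: model, assumptions, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling in cpmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The problem

Connectome-based predictive modeling (CPM) asks whether an individual's
resting-state functional connectome — the matrix of pairwise Pearson
correlations between parcellated fMRI time courses — carries enough
information to predict a scalar phenotype measured in the same person:
a regional tau PET standardized uptake value ratio (SUVR), an amyloid-β
distribution volume ratio (DVR), or a cognitive score such as the MMSE.
cpmr implements that analysis end to end for cohorts in which each subject
contributes a small number of short resting-state runs (by default two runs
of 120 TRs at TR = 3 s, with 4 initial T1-stabilization frames), on a
449-node parcellation: 400 cortical nodes organized into the 17 canonical
cortical networks, 17 cerebellar nodes, and 32 subcortical nodes.

Because the motivating cohort (carriers of a fully penetrant autosomal
dominant Alzheimer's mutation and their non-carrier relatives) is private,
cpmr ships a first-class synthetic cohort generator. Every stage of the
pipeline is exercised and quantitatively verified on simulated data with
known ground truth; nothing in the package depends on access to real
imaging data.

## From time series to connectome

Per run, preprocessing applies, in order:

1. **Dummy-frame removal** — the first `dummy_frames` (default 4) TRs.
2. **Motion censoring** — frames with framewise displacement (FD) strictly
   above `fd_threshold_mm` (default 0.2 mm) are dropped. A run with fewer
   than 10 surviving frames is an error, not a silent degenerate input.
3. **Demeaning** — each node's series is centered over the run's surviving
   frames.
4. **Global-signal regression (GSR)** — the run's global signal is the
   unweighted mean across all parcel series at each frame; it is regressed
   out of every node by simple least squares and the residuals kept.

Runs are then concatenated along frames, and the connectome is the Pearson
correlation of every node pair (diagonal 1). The steps are ordered so that
spike frames can contaminate neither the run mean nor the global-signal
regressor; the underlying sources list the steps but not their
interleaving, so this ordering is a package decision, exposed through
configurable arguments. The global signal is the whole-parcellation mean
(not cortex-only); correlations are used raw, with no Fisher
z-transformation, because downstream network strengths sum raw FC values.

Edges live in a canonical vectorization: the strict upper triangle in
row-major order — pairs (i, j), i < j, 0-based, ascending i then j —
giving n(n−1)/2 edges (100,576 for n = 449). All masks, consensus maps and
exports share this indexing, and the round trip matrix ↔ vector is exact.

## The CPM core

On a training set, each edge's FC values are Spearman-rank-correlated with
the phenotype. Two-sided p-values use the t approximation
t = ρ√((n−2)/(1−ρ²)) with average ranks for ties; at the default threshold
p < 0.01 and 28 training subjects, an edge enters a mask iff |ρ| exceeds
about 0.4785. Edges with ρ > 0 form the positive mask, ρ < 0 the negative
mask — strictly sign-partitioned, never both. No multiple-comparison
correction is applied at this stage; the cross-validation and permutation
null downstream are what license inference. The per-subject **network
strength** is the sum of FC values over the mask's edges, and a univariate
ordinary-least-squares fit of phenotype on strength gives one model per
tail. Predictions for held-out subjects are `intercept + slope × strength`.

Degenerate situations (an empty mask on an unlucky fold, or constant
strengths) flag the model and fall back to predicting the training-target
mean, so k-fold pooling stays well-defined instead of aborting; degenerate
fold-models are counted and reported.

## Cross-validation, iteration averaging, permutation null

Subjects are split into k balanced folds uniformly at random (k = 8 for a
32-subject group, giving folds of 4; k = 7 for 35, giving folds of 5).
Each fold is predicted by a model trained only on the other folds; no
subject is ever in both sides. Pooled accuracy is the Pearson r between
actual and predicted values over all subjects, per tail. Because the fold
assignment is random, the whole k-fold run is repeated (default 50
iterations) with fresh fold randomizations and the accuracies averaged
arithmetically (not Fisher-z); per-edge selection counts are accumulated
across all fold-models for consensus mapping.

Significance comes from a permutation null: phenotype values are shuffled
across subjects, the full k-fold run is re-executed per shuffle (default
1000 permutations, one fresh fold randomization each — not 50 iterations
per permutation, a deliberate compute-conservative choice standard in the
CPM literature), and

p = (1 + #{null r ≥ observed r}) / (1 + n_perm),

the add-one rule, so p is never exactly 0. All randomness derives from one
master seed via deterministically spawned child seeds; identical
configuration and seed reproduce outputs byte for byte.

A motion-control run repeats the identical pipeline with each subject's
mean FD (over retained frames) as the target, to check that apparent
phenotype predictions do not ride on head motion.

## Consensus masks, degree, and network aggregation

For interpretation, the per-edge selection frequency over all fold-models ×
iterations is binarized at a frequency cutoff (default 0.5 — the sources
never state how the "averaged mask" was thresholded, so the cutoff is
exposed and the raw frequency map always exported). On the binary mask,
node degree counts incident edges (maximum n−1 = 448), Σdegree = 2|mask|
exactly, and the network-pair matrix counts edges between each pair of
parcellation groups (within-network pairs counted once), conserving |mask|.
Cerebellar nodes share the 17 cortical network labels; the 32 subcortical
nodes aggregate under their own structure names and are also summarized
separately. Both mean and summed degree per network are emitted, since
either may be wanted for reporting.

## The synthetic cohort generator

The generator works forward from phenotype to connectivity: a phenotype is
drawn per subject (normal, configurable moments), and the subject's target
correlation matrix is a block baseline — `baseline_correlation` (default
0.25) within each network, 0 across networks — plus, on each planted edge,
`effect_size` × the standardized phenotype (sign-flipped for negative-tail
edges). The coupling saturates at ±2 SD of phenotype and planted values are
clamped to |r| ≤ 0.97: the generator's feasibility envelope is designed
around the ±2 SD range (the spec-level invariant |baseline ± 2·effect| < 1),
and extreme draws should not demand impossible correlations. Frames are
sampled as zero-mean multivariate normal draws from the target matrix.

Because editing entries of a correlation matrix can break positive
semidefiniteness, each target is repaired by Higham-style alternating
projections between the PSD cone and the constraint set (unit diagonal,
entries in [−1, 1], planted values held fixed), tolerance 1e-8, at most 100
sweeps. If the final PSD matrix still sits more than 0.05 from any planted
edge's requested value, the specification is declared infeasible and
generation fails loudly. Two structural guards in `plant_edges()` keep
realistic configurations feasible: planted node degree is capped (default
2), and a planted cycle may only close over at least 8 nodes — hub nodes
with several strong couplings, and short cycles with inconsistent sign
patterns, are exactly the configurations whose demanded edge values have no
PSD completion.

Motion is simulated as FD spikes (Bernoulli per frame, default rate 0.05,
magnitude 0.6 mm against a 0.02–0.15 mm baseline; the first frame's FD is
n/a in the fMRIPrep dialect). Spike frames are corrupted with additive
noise at 3× the signal SD, so censoring has a measurable benefit — the test
suite verifies that censored connectomes recover the subject's target
matrix better than uncensored ones. The per-subject target matrices are
retained on the cohort object for exactly this kind of scoring.

What the generator does **not** emulate: hemodynamic (BOLD) forward
dynamics, temporally autocorrelated noise, realistic head-motion
kinematics, site or scanner effects, and any causal claim about whether
pathology drives connectivity or vice versa — the forward model is a
testing convenience. Passing recovery tests therefore show that the
pipeline's inference machinery is correct and calibrated, not that real
tau or amyloid burden is predictable at any particular accuracy.

## Verification strategy and problem sizes

The test suite verifies each operation against an independent oracle:
network strength against a brute-force double loop over the full matrix,
OLS coefficients against closed-form normal equations, node degree against
adjacency row sums, Spearman ρ/p against `stats::cor.test` per edge and
against exhaustive permutation enumeration at n = 6, the summary-statistic
t-test against `t.test` on raw samples constructed to match the summaries,
and published group-difference t statistics recomputed from (n, mean, SD)
triplets alone.

Pipeline-level checks run on simulated cohorts scaled to keep the full
suite fast while preserving the designed study conditions where they
matter:

- **Recovery**: 20 cohorts of 64 subjects, 60 nodes, 30 planted edges per
  tail, effect size 0.3, two runs of 200 usable frames; the consensus
  positive mask recovers ≥ 80% of planted positive edges and the iterated
  cross-validated accuracy beats a 200-permutation null (p < 0.05) in at
  least 18 of 20 seeds. The observed statistic averages 10 fold
  re-randomizations; the default of 50 is unchanged for real analyses.
- **Calibration**: 100 cohorts with effect size 0; the permutation p
  (100 permutations) is uniform — the fraction below 0.05 stays inside the
  binomial 95% band. This check runs with a single cross-validation
  iteration as the observed statistic, which makes the observed and
  permuted accuracies exchangeable under the null, so uniformity is exact
  by construction; with a multi-iteration mean as the observed statistic
  the observed value has smaller variance than single-run nulls and the
  percentile is no longer exactly uniform (it becomes conservative). That
  subtlety is worth knowing when interpreting real-data p-values computed
  with the default settings.
- **Selection consistency** is scored on connectomes computed from the raw
  simulated frames (no GSR): GSR mixes the global mean — which contains the
  planted phenotype-coupled signal — back out of every node, spreading weak
  phenotype associations across many edges. On GSR-processed cohorts the
  apparent "false-positive" edge rate at p < 0.01 rises to roughly 15%,
  not because selection is broken but because those associations are
  genuinely present in the regressed data. This is a real property of
  global-signal-regressed pipelines, and a caveat for interpreting mask
  sizes on real data.

## Numerical choices and edge cases

- Spearman p-values use the t approximation with average ranks; exact
  enumeration is reserved for test oracles at tiny n.
- Edges with zero variance across training subjects are excluded from
  selection; zero-variance nodes make the connectome fail loudly with the
  node named.
- FD equal to the threshold is retained (censoring is strictly `>`);
  a missing FD (first frame) counts as 0 and is never censored.
- Pooled accuracy r is defined as 0 (and flagged) when pooled predictions
  are constant, which keeps permutation counting well-defined when every
  fold degenerates.
- Fold sizes differ by at most one; `k` larger than the subject count is an
  error.
- Seeds: every user-facing entry point takes one integer seed; internal
  child seeds are drawn deterministically from it and stay below 2³¹.

## Known limitations

Thresholded Spearman selection plus univariate OLS is the faithful CPM
recipe, not the best possible predictor; regularized or nonlinear variants
are out of scope. The permutation scheme re-randomizes folds once per
permutation rather than averaging 50 iterations per permutation. The
generator's multivariate-normal frames have no temporal autocorrelation, so
effective sample sizes per frame are optimistic relative to real BOLD data.
Group-level t statistics recomputed from published summary triplets inherit
the rounding of those summaries.
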