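---
title: "Evolving QTL-analysis pipelines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving QTL-analysis pipelines: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoqtl)
```

## The problem

A standard QTL analysis regresses a continuous trait on biallelic genotypes
coded additively (0/1/2 copies of one allele). That single modelling decision
hides several others a quantitative geneticist actually makes: which
inheritance model each locus follows (dominance, recessivity, heterosis,
over- or underdominance), which loci deserve to stay in the model (allele- and
genotype-frequency filters, univariate association filters), and which
regression family relates genotype to phenotype. `autoqtl` treats that whole
decision chain as a search space: a *pipeline* is an ordered chain of genotype
re-encoders and feature selectors ending in exactly one regression root, and
genetic programming (GP) searches over pipelines, their order, and their
hyperparameters globally instead of applying them in a fixed human order.

## The pipeline model

A pipeline is an expression tree flattened to a phase chain plus a root:

* **Encoders** re-map every genotype in the data through a total map on
  `{0,1,2}`. The five non-additive maps are fixed in `encoding_tables`:
  dominant `0,2,2`, recessive `0,0,2`, heterosis `0,2,0`, overdominance
  `0,2,1`, underdominance `1,0,2`. Heterosis equalizes the homozygotes;
  dominant, recessive and heterosis collapse three genotype values to two
  ("2-level"), over- and underdominance permute all three ("3-level"). The
  exact value assignments are a convention of this package, kept in one table
  so they are trivially replaceable; the 2-level/3-level classification and
  the homozygote-equalizing property of heterosis are the load-bearing facts.
  Encoders compose left to right, and compositions can reach maps (including
  the degenerate constant map, reported as "1-level") that no single encoder
  expresses.
* **Selectors** remove loci. `VT` keeps a locus when its population variance
  is *strictly* greater than the threshold (grid 0–0.35 by 0.05), so
  threshold 0 removes constants. `SP` keeps the top percentile of loci by the
  univariate F-regression score `F = r²/(1−r²)(n−2)` (grid 5–95% by 5%); the
  kept count is `max(1, round(p/100·m))` with half-up rounding and
  lower-index tie-breaks, so a selector can never empty the matrix on its
  own. `GF` removes a locus when any genotype frequency falls below the
  threshold (grid 0–0.35 by 0.05); frequencies are computed over the genotype
  values *present* in the column. The alternative — counting absent classes
  as frequency zero — would delete every 2-level-encoded locus at any
  positive threshold and make encoder+GF pipelines impossible, which
  contradicts their observed usefulness.
* **Roots**: ordinary least squares (`LR`, no hyperparameters), a CART
  regression tree (`DT`: `max_depth` 1–10, `min_samples_leaf` 1–20,
  `min_samples_split` 2–20), or a random forest (`RF`: `bootstrap` T/F,
  `max_features` 0.05–1 by 0.05, the two leaf/split sizes, 100 trees —
  the tree count is a constant, not a tuned hyperparameter). Trees are
  grown by `rpart` with `cp = 0` (no cost-complexity pruning, the raw CART
  semantics of the hyperparameters). The forest is bagging of such trees
  with a per-**tree** feature subsample of `ceil`-rounded fraction
  `max_features`; per-*split* subsampling is not exposed by any suitable
  tree backend, and the per-tree variant keeps an exact identity that the
  test suite exploits: a forest with `bootstrap = FALSE`,
  `max_features = 1` is the corresponding single tree.

Selectors are always fit on the training partition and their masks applied
unchanged to test and holdout partitions — no leakage.

## Fitness and selection

The data are split once per run: `floor(0.2 n)` samples to a holdout set used
only to re-score the final front, and the remainder halved into train and
test (odd sample to test; the fixed rounding makes every run reproducible).
Each pipeline is fit on train and scored by two maximized objectives:

* test-partition `R² = 1 − SSres/SStot` (negative values allowed), and
* the difference score `DS = (1/|train R² − test R²|)^{1/4}`, which
  penalizes overfitting. The absolute difference is floored at `1e−8`, so
  `DS ∈ (0, 100]` and a pipeline with equal train and test R² scores exactly
  100 rather than dividing by zero.

Evolution runs with population 100, offspring 100, mutation rate 0.9,
crossover rate 0.1 and 25 generations by default. Per offspring, exactly one
of mutation (three equally likely kinds: uniform node replacement or
hyperparameter re-draw, insert, shrink) or crossover is applied. Parents are
chosen by crowded binary tournament — lower non-domination rank wins, ties
go to the larger crowding distance — on top of NSGA-II survival over
parents plus offspring. Fitness-biased parenting matters here, not just as
the standard NSGA-II idiom: with uniform parent draws the search loses its
grip on the high-R² linear corner of the front at small population sizes
and can fail to re-derive the plain multiple-regression pipeline that
anchors the front's R² end; tournament parenting makes fitter pipelines
contribute more of their phases to offspring, which restores that behaviour
at every search scale we test. Crossover is one-point at phase boundaries and
requires the parents to share a phase operator *class* (both have an encoder
phase or both a selector phase); only the first offspring is kept, and
ineligible pairs fall back to cloning. Uniform mutation re-draws until the
operator or hyperparameter actually changes — a no-op would waste an
offspring — and the only admissible no-op is shrink on a phase-less
pipeline, since the root can be swapped but never deleted.

The Pareto **archive** is cumulative over all evaluated pipelines
(hall-of-fame semantics), deduplicated by pipeline structure, and pruned to
the non-dominated set after every generation. A per-generation
population-restricted front is the other defensible reading; the cumulative
one was chosen because it preserves every optimum the search ever visits and
reproduces the validation behaviour below under either reading. Pipelines
whose selectors remove every locus get sentinel fitness `(−∞, −∞)` instead
of raising mid-run, and can never enter the archive. All tie-breaks
(non-dominated sorting, crowding-distance ties, SP score ties) fall back to
insertion index, and every stochastic component — the split, pipeline
drawing, variation, forest resampling — is a pure function of the run seed,
so identical configurations reproduce bit-identical archives.

## Shapley locus importance

Each archive pipeline gets a per-locus importance: the mean absolute Shapley
value over evaluation samples, computed in the pipeline's *transformed*
feature space with the transformed training partition as background
distribution and the transformed test partition as evaluation points (so
importance measures generalizable contribution, not training fit), then
reported against original locus identifiers. Loci removed by the pipeline's
selectors are exactly 0 by construction. For `LR` roots the closed form
`φⱼ = βⱼ(xⱼ − mean(background))` is exact. For tree roots a seeded
permutation-sampling estimator is used (the environment offers no TreeSHAP
implementation, and the sampling estimator's telescoping construction makes
the efficiency axiom — values summing to prediction minus baseline — hold
exactly for any sample size); defaults (16 permutations, up to 100
evaluation and 200 background rows) put it above 2,000 model evaluations per
explanation. Across pipelines, scores are averaged per locus with the
standard error of the mean, zeros included.

## The simulation toolkit

The generator emulates the structure of a small panel of
genome-wide-significant QTL for a continuous trait in a large cohort:

* `simulate_hwe_genotypes()` draws loci i.i.d. under Hardy–Weinberg
  proportions at a configurable minor allele frequency (default 0.5, the
  frequency at which the XOR model is exactly marginal-free).
* `simulate_qtl_dataset()` adds standard-normal per-locus additive effects
  and Gaussian noise calibrated analytically so the full-data multiple-LR
  R² is ≈ 0.10 — the order of magnitude a real 18-QTL panel explains of a
  residualized trait, and the default study condition throughout.
* `xor_penetrance()` is 1 iff exactly one locus of the pair is heterozygous.
  This is the symmetric 0/1 two-locus table whose HWE(0.5)-weighted marginal
  penetrance is 0.5 for all six single-locus genotypes, i.e. pure two-way
  epistasis with no marginal effect; that marginal property, not the
  particular cell layout, is what the downstream experiments rely on, and
  the table is again a one-line replaceable convention.
* `inject_xor_pair()` matches penetrance-1 combinations to the top half of
  phenotype ranks by jointly permuting the pair's rows — the strongest
  possible XOR signal — preserving the two-locus combination multiset (and
  therefore all genotype and allele frequencies) bit-exactly.
  `shuffle_fraction()` weakens the signal by re-permuting the combinations
  among a random fraction of rows, again frequency-preserving; shuffling
  operates on row pairs rather than single cells precisely to keep that
  exactness. `calibrate_to_target_r2()` bisects on a common shuffle fraction
  (≤ 20 iterations, ±0.01 stopping tolerance) until a fixed reference
  forest probe (`bootstrap = TRUE`, `max_features = 0.25`,
  `min_samples_leaf = 5`, `min_samples_split = 10`, 100 trees, seeded)
  detects the target test R²; an unreachable target reports the unshuffled
  ceiling instead of looping. The probe is a package convention, isolated as
  an argument.
* `build_interaction_ladder()` produces the 0..k-interaction series in two
  modes: `replace_noise` (all columns permuted first, so interactions
  replace pure noise) and `replace_main_effects` (each step permutes two
  intact columns, breaking their main effects, then injects the pair).

What the generator does **not** emulate: linkage disequilibrium between
loci, relatedness structure, missing genotypes, incomplete penetrance, and
higher-order epistasis. Passing tests on this generator therefore show that
the search behaves as designed under clean HWE, independent-locus
conditions; they do not certify behaviour under population structure or LD,
which real cohorts have and which is assumed to be handled upstream
(residualized phenotypes, relatedness-corrected).

## Problem sizes used in validation

The replication experiments (`qtl_replicate()`) default to a reduced scale
chosen so the full ten-seed suite completes in minutes on one CPU: 1,000
samples, 18 loci, total explainable R² ≈ 0.10, population 20, offspring 20,
10 generations (the full-scale settings are population 100, offspring 100,
25 generations on 5,566 samples). The interaction-ladder experiments are
probe-only (a fixed reference forest and a plain linear model, no GP), so
they run at the full benchmark cohort size of 5,566 samples: the flatness
of the linear model's test R² is an absolute statement, and LR's
out-of-sample bias scales as −m/n on the training half, which would smear
any ±0.02 band at 1,000 samples. At these scales, across seeds 0–9:

* **validate** — on pure-additive data the final archive contains an
  LR-rooted pipeline whose test R² reaches the multiple-LR baseline on the
  same test split (≥ baseline − 0.005; the bare-LR pipeline scores it
  exactly, and pipelines whose selectors improve generalization may exceed
  it);
* **xor9** — with nine calibrated XOR pairs and no main effects, the best
  machine-learning-rooted archive pipeline out-scores the best LR-rooted one
  in at least 9 of 10 seeds;
* **ladder** — the reference-forest detectable R² increases monotonically
  in the number of interactions while LR stays within ±0.02 of zero.

These are the properties asserted by `tests/testthat/test-acceptance.R`; the
vignette states no number the tests do not themselves compute.

## Degenerate inputs and numerical notes

Constant phenotypes are rejected everywhere (R² is undefined). Singular
regression designs (e.g. duplicated or collapsed loci) are resolved by the
pivoting least-squares solution with aliased coefficients set to zero rather
than erroring. A selector chain that empties the matrix yields sentinel
fitness, not an exception. Phenotype ties at the injection median are broken
by sample index (stable order). `R²` uses the scored partition's own mean in
`SStot`, so holdout values can be negative — that is information about
overfitting, not an error.

## Known limitations

Per-locus (column-specific) encodings are out of scope — encoders act
uniformly across loci, matching the operator definition. Discrete phenotypes
(classifier roots) are not supported. Evaluation is single-threaded; the
fitness cache (structural memoization) is the only acceleration. Shapley
interaction indices are not computed; similar importance of two loci is
consistent with, but not proof of, an interaction between them.
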