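---
title: "Regression-based reconstruction of missing landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based reconstruction of missing landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorec)
```

## The problem

Skeletal material reaching anthropologists, paleontologists, and forensic
scientists is routinely damaged. When a bone's shape is recorded as a
configuration of 3D landmarks, damage means missing landmarks, and a
natural question is how faithfully those can be estimated from the rest of
the bone plus a reference sample of complete specimens. `morphorec`
implements the regression method (RM) for this task — every missing
coordinate is predicted by a multiple linear regression on all present
coordinates, trained across an undamaged reference sample — together with
the shape-space machinery the method sits on and a simulation framework
that measures its accuracy under controlled damage scenarios on a
zygomatic-like 30-landmark scheme (7 fixed landmarks, 23 surface
semilandmarks).

## Shape-space machinery

**Generalized Procrustes analysis.** Configurations are centered, scaled
to unit centroid size, and iteratively rotated onto a consensus
(initialized as the first specimen after standardization), which is
recomputed as the renormalized coordinate-wise mean until the partial
Procrustes distance between successive consensus shapes falls below `tol`
(default `1e-10`, cap 100 iterations). Rotations are the SVD (Kabsch)
solution with the determinant forced to +1: reflections are never
introduced by alignment. Antimere (left/right) pooling is instead an
explicit, declarative input step (`reflect_configuration()`).

**Procrustes distance.** All accuracy reporting uses the *partial*
Procrustes distance: both configurations scaled to unit centroid size,
optimally rotated, root summed squared difference. It is computed per pair
(`pairwise_opa`), so reported distances do not depend on the common
alignment; a `common_space` mode (plain root sum of squares of aligned
coordinates) exists for diagnostics such as outlier screening. The
residual is evaluated explicitly after rotation rather than through the
algebraic shortcut `2 - 2 tr(Σ)`, which loses half the significant digits
to cancellation near zero.

**Semilandmark sliding.** The 23 surface points carry no point-wise
homology, so they are allowed to slide within estimated tangent planes to
minimize the thin-plate-spline bending energy of each specimen's
displacement from the consensus. The 3D TPS kernel is `U(r) = r` with the
sign convention that makes the quadratic form positive semidefinite
(kernel block `-||p_i - p_j||`); affine fields lie exactly in its null
space. Tangent planes are fitted as the two leading principal axes of the
landmark plus its 8 nearest landmarks (neighbor identity taken from the
consensus; the plane fitted on each specimen's own aligned coordinates),
with a doubled neighborhood as fallback for degenerate clouds. Each
sliding iteration solves, per specimen, the exact linear least-squares
problem for all tangent offsets jointly; fixed landmarks never move. There
is no mesh in this pipeline, so slid points are not re-projected onto a
surface — a deliberate deviation from mesh-based workflows, appropriate
because the generator produces landmarks, not surfaces.

Because the sliding target (the consensus) and with it the TPS kernel are
recomputed after each iteration, the total energy converges into a small
oscillation band (~0.1% relative on default synthetic data) rather than to
a strict fixed point. The implementation therefore monitors the total
energy and rejects any iteration that would raise it, so the reported
energy trace is non-increasing by construction; in practice one or two
passes do essentially all the work. Within an iteration the per-specimen
solve is an exact quadratic minimization, so the before/after energy drop
is guaranteed.

## The regression method

Given a damage pattern (a set of missing landmark indices), the model is
trained on the GPA-aligned, slid reference sample: ordinary least squares
with intercept of all missing coordinates on all present coordinates,
solved by SVD. Two design choices matter and both exist to make training
and prediction *gauge-consistent*:

1. **Training happens in the prediction gauge.** A damaged specimen can
   only be aligned on its present landmarks, so each reference specimen is
   re-superimposed onto the consensus by its present subset (full
   similarity fit) before the design matrix is built, and coordinates are
   expressed relative to the present-landmark centroid. GPA coordinates
   satisfy exact linear constraints (centering over all landmarks,
   rotational first-order conditions) that a present-subset-aligned input
   cannot satisfy; if the design is built in the GPA gauge, those
   constraints become exact collinearities whose arbitrary resolution
   leaks into predictions. In the prediction gauge every exact dependency
   of the training design is satisfied by every prediction input, so exact
   linear structure in the data is predicted exactly (verified in the
   tests to ~1e-8).
2. **Predictor reduction only when necessary.** When `3 k_present + 1`
   reaches the reference size, predictors are reduced to principal
   component scores retaining `min(n - 2, components explaining 99% of
   variance)`; otherwise plain (pseudo-inverse) OLS is used. The reduction
   applied is recorded in the fitted model. Ridge penalties are not used —
   the method stays a linear regression. A zero-variance design (all
   reference shapes identical to numerical precision; singular values
   below an absolute floor of `sqrt(n) * 1e-8` on unit-size shapes)
   degrades to an intercept-only model, i.e. consensus substitution, which
   is the correct limit; with the SVD solver a rank-deficient design after
   reduction is structurally impossible.

Imputation superimposes the damaged specimen's present landmarks onto the
consensus (with scaling — reference shapes are unit-size, so the
specimen's size is nuisance), feeds the gauge-consistent covariates to the
regression, and inserts the predictions. The similarity transform used is
returned so completions can be mapped back to original specimen space.
Predicted points are not re-slid: prediction is the endpoint.

## The damage-simulation study

Three damage cases mirror progressively larger damaged regions on the
zygomatic scheme: Case 1 deletes fixed landmarks {1, 2} (zygomatic
process), Case 2 deletes {4, 5, 7} (orbital margin), Case 3 deletes
semilandmarks {16–21} (zygomatic body). For each case, 30 targets are
sampled without replacement (per-case seeds derived from the master seed
as `seed + 104729 * case_index`, so cases are independently reproducible;
a shared-target design is available). For every target:

1. the remaining specimens are aligned and slid afresh — strict
   leave-one-out; the target never influences the reference consensus,
   sliding, or regression (verified by a poisoning test);
2. the target is standardized exactly as any specimen in the original
   processing chain would be: superimposed onto the leave-one-out
   consensus and its semilandmarks slid against it
   (`slide_to_reference()`). These coordinates are the *true* target. An
   early design that deleted landmarks from the completely raw target
   instead was abandoned: the reference's sliding absorbs tangential
   digitization noise that a raw target still carries, and the resulting
   covariate shift degraded predictions so badly that the regression could
   lose to the mean-shape template — an artifact of mismatched processing,
   not a property of the method, since in the original workflow every
   specimen (future targets included) passes through the same
   GPA-plus-sliding standardization before damage is simulated;
3. the case's landmarks are deleted, the model fitted on the 149, the
   target imputed;
4. two partial Procrustes distances are recorded: d(true, predicted) and
   d(true, reference consensus) — the latter is what one would accept by
   using the mean shape as a template, and the reference consensus is the
   leave-one-out consensus of the 149.

Per case, a two-sample t-test (Welch by default; the distances are in fact
paired per target, so the paired statistic is emitted as a supplementary
column) compares d(true, predicted) against d(true, consensus). Across
cases, a one-way ANOVA on d(true, predicted) with Tukey HSD locates which
damage patterns reconstruct best. All statistics are written as explicit
formulas (with `pt`/`pf`/`ptukey` for the distributions) and are exactly
recomputable from the exported records table; base R's `t.test`, `aov`,
and `TukeyHSD` serve as independent cross-checks in the test suite, which
also verifies null calibration (type-I error within [0.035, 0.065] at
α = 0.05 over 2,000 replicates).

Outlier screening (distance of each aligned specimen to the consensus,
flag above Q3 + 1.5 IQR) marks review candidates only; nothing is excluded
automatically.

## The synthetic generator

The generator exists so every downstream stage is testable without any
external data. It emulates, with deliberate simplifications, the
statistical structure such a study rests on:

- **Template.** A deterministic 30-point layout on a smooth curved
  quadrilateral patch (~40 mm extent, centroid size ≈ 90 mm), with the
  fixed landmarks at suture-corner regions and the semilandmarks on an
  interior grid whose central 3 × 2 block is indices 16–21 — so the three
  damage cases delete spatially clustered regions of realistic size.
- **Covariance.** Two layers. (1) Global: m = 8 smooth modes (leading
  eigenvectors of a squared-exponential kernel with length scale 0.3 ×
  template diameter, applied per axis), with geometrically declining scales
  3 mm × 0.6^(j−1) — physically close landmarks co-vary, which is precisely
  the redundancy the regression exploits, and the low rank keeps the
  90-dimensional covariance well-conditioned at n ≈ 150. (2) Local: a
  short-range surface-relief Gaussian field along the semilandmark normals
  (marginal sd 1.2 mm, length scale 4 mm), emulating tubercle and
  muscle-insertion relief of the zygomatic body. The local layer matters
  for the damage-extent effect: sliding couples all landmarks through the
  bending-energy solve, so slid semilandmark positions are largely
  interpolable from the rest of the bone, and a generator with only global
  smooth modes makes a missing contiguous patch almost free to
  reconstruct. Short-range normal relief survives tangential sliding, is
  partially predictable from immediate neighbors, and is genuinely lost
  when an entire patch is gone — which is also the anatomical explanation
  usually offered for why contiguous damage to the zygomatic body
  reconstructs worst. Fixed (sutural) landmarks carry no local relief;
  their positions are set by bone boundaries.
- **Populations.** Two groups matching the study composition (Italian 119,
  African American 31); the second carries a small smooth mean offset
  (norm 1.2 mm, ~1.3% of centroid size — the generator enforces offsets
  below 20% of centroid size). No effect sizes are published for such
  offsets; this one is a free parameter chosen to be visible but small
  against individual variation.
- **Digitization noise.** Independent per-coordinate noise whose scale
  averages ~0.5% of centroid size but differs by landmark type: 0.35 mm at
  the sharp orbital-margin points (4, 5, 7), 0.40 mm at the frontal and
  maxillary corners, 0.55 mm at the extremal temporal-process suture
  points (1, 2 — extremal points on a curving suture are hard to place
  repeatably) and for surface semilandmarks, whose placement on a smooth
  surface is intrinsically less repeatable. A per-specimen lognormal
  precision multiplier (log-sd 0.35) models varying digitization quality
  across specimens. These choices reproduce the regime the study design
  presupposes: reconstruction error well below inter-individual distance,
  small damage comparable across locations, and accuracy dropping clearly
  for contiguous damage to the semilandmark patch.
- **Nuisance.** Per-specimen uniform random rotation (proper only —
  alignment never corrects reflections, and antimere reflection is an
  explicit I/O step), translation, and lognormal centroid-size dispersion
  (log-sd 0.05). Shape randomness is drawn before nuisance randomness, so
  the same seed yields the same shapes with nuisance on or off — the basis
  of the end-to-end invariance tests.

With these defaults the default study (150 specimens, 3 cases × 30
targets) lands at mean distances to the consensus around 0.09 and
reconstruction errors around 0.015–0.025, and reproduces the expected
qualitative pattern: regression beats the consensus template decisively in
every case, Cases 1 and 2 (two and three missing landmarks in different
regions) are statistically indistinguishable, and Case 3 (six contiguous
missing semilandmarks) is separated from both.

What the generator does *not* emulate: anatomical realism of the template
beyond clustering/contiguity, meshes or surfaces (hence tangent planes
estimated from the landmark cloud), asymmetric or articulated structures,
and non-Gaussian shape variation. Passing tests therefore demonstrate the
pipeline's correctness and the method's behavior under the modeled
covariance regime, not performance guarantees on any particular real
collection.

## Numerical choices and degenerate inputs

- GPA: `tol = 1e-10`, `max_iter = 100`; non-convergence returns a flagged
  result with a warning rather than an error.
- Sliding: 3 iterations by default, early stop at relative energy change
  below `1e-6`; a numerically singular tangent system is ridge-regularized
  (`1e-8` × mean diagonal) with a warning. Tangent frames are estimated
  once per call — per-iteration sliding displacements are far smaller than
  the neighborhoods the planes are fitted to.
- Duplicate landmarks make the TPS system singular and are rejected with
  the offending indices named; collinear present subsets and rank < 2
  configurations are rejected before any superimposition.
- A degenerate (all-coincident) shape reports centroid size 0 with a
  warning; zero-variance statistical inputs error rather than returning
  NaN.
- Problem sizes in the tests (reference samples of 149, 30 targets per
  case, 10 replicates for the cross-case pattern, 2,000 null-calibration
  replicates, 20,000 draws for the covariance oracle) were chosen so the
  full suite completes in minutes while keeping Monte-Carlo error well
  inside the asserted tolerances.

## Known limitations

- Tangent-plane sliding without surface re-projection can drift points off
  a real surface for large displacements; with the noise scales modeled
  here displacements are small.
- The regression is trained per damage pattern; arbitrary per-specimen
  missingness patterns require one model per pattern.
- Curve semilandmarks (one-dimensional sliding), TPS-interpolation
  imputation, and iterative multiple imputation are out of scope; mean
  substitution exists only as the comparison baseline inside the study
  driver.
- The t-test treats the two distance sets as independent samples even
  though they are paired per target (the paired statistic is emitted
  alongside); this mirrors the comparison design the study framework is
  built to evaluate.
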