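---
title: "Genetic energy-layer optimization for dynamically collimated proton arcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic energy-layer optimization for dynamically collimated proton arcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnarc)
```

## The planning problem

Proton arc therapy delivers pencil beam scanning (PBS) spots while the
gantry sweeps an arc. Because the gantry moves during delivery, each
discretized gantry angle — a *control point* — can deliver only a single
beam energy (equivalently, a single range in water). Plan quality then
hinges on a combinatorial question that conventional fluence optimizers do
not answer: *which energy should each control point carry?* On top of that
sits the usual continuous problem of choosing non-negative spot weights,
and, when a dynamic collimation system (DCS) is available, the per-beamlet
question of where to park the trimmer blades that sharpen each spot's
lateral penumbra.

`dnarc` implements this three-layer problem as a staged genetic algorithm
wrapped around projected-gradient fluence optimization, with per-beamlet
erf-edge collimation applied to the winning plan. Everything runs on
synthetic voxel phantoms built by the package itself, so the full pipeline
is testable without any patient data.

## The objective

Plans are scored by a quadratic dose-volume-histogram (DVH) penalty,

$$
F=\sum_{k=1}^{K}\frac{1}{T_k}\sum_{i\in\tau_k}\Big[
\beta_k^{+}\,c^2_{(0,\infty)}(d_i-d_k^{+})
+\beta_k^{-}\,c^2_{(-\infty,0)}(d_i-d_k^{-})
+\beta_k^{V+}\,c^2_{(0,\Delta D_k^{V+})}(d_i-d_k^{V+})
+\beta_k^{V-}\,c^2_{(\Delta D_k^{V-},0)}(d_i-d_k^{V-})\Big],
$$

where $\tau_k$ are the $T_k$ voxels of structure $k$, $c_{(a,b)}(x)$
passes $x$ unchanged inside $[a,b]$ and clamps it to zero outside, the
first two terms are plain overdose/underdose penalties, and the last two
are dose-volume penalties whose window width $\Delta D$ is the gap between
the current DVH dose at volume level $V$ and the desired one. All
constraints are soft. The gradient with respect to beamlet weights follows
by the chain rule through the sparse dose-influence matrix,
$\partial F/\partial w_j=\sum_i (\partial F/\partial d_i)\,D_{ij}$.

Two numerical choices matter here:

* **Window freezing.** $\Delta D$ windows are recomputed once per outer
  weight-optimization iteration and frozen inside the line search. The
  frozen objective is discontinuous exactly at a window's far edge (a
  voxel leaving the window drops a finite penalty), which is why the
  finite-difference validation of the gradient samples instances away
  from window edges.
* **Per-structure thresholds.** The per-voxel thresholds $d^{\pm}_{i,k}$
  are held constant within a structure; the interface would accept
  per-voxel maps, but constant thresholds are the simplest faithful
  reading and all defaults use them.

## The genetic search

A candidate plan (*member*) is a haploid chromosome: one energy-layer
index per control point. Each generation,

1. every member's weights are re-optimized (warm-started) by projected
   gradient descent with a Barzilai–Borwein step and backtracking,
2. members are ranked by $F$ (ascending; ties broken by age; fitness is
   compared at 9 significant digits so ranking is invariant to
   floating-point summation order),
3. the best member (*alpha*) is cloned into the next generation,
4. non-runt members each produce one child with a partner drawn with
   rank-linear probability $p(r)=2(P-r+1)/(P(P+1))$, never themselves;
   each unlocked locus comes from either parent with probability 1/2, and
   each locus's weight block warm-starts from whichever parent supplied
   that allele (weights persist with their energy choice — copying the
   other parent's block would not even have the right length when layers
   differ),
5. the worst $R$ members (*runts*) are replaced by fresh random members.

The arc is refined in *evolutionary stages*: stage $s$ has $2^s+1$ evenly
spaced control points, so stage 1 is the arc's two ends plus its middle,
and every later stage inserts midpoints. Only that reading reproduces the
schedule 3 → 5 → 9 → 17 → 33 → 65 → 129 over seven stages of a 140° arc
(1.1° spacing at the end). Energies decided in earlier stages are locked;
their weights keep being re-optimized. After the last stage the alpha
receives a longer weight polish, optional per-beamlet collimation with a
weight re-optimization (the genetic search is not repeated after
collimation), and a final normalization that scales all weights by one
global factor so the target D95 equals the prescription as read off the
package's binned DVH curve (exact-quantile scaling plus one fixed-point
refinement against the 0.1 Gy-binned readout).

Hyperparameter defaults — population 10, 15 generations per stage, 2
runts, 25 weight-optimizer iterations per generation, 200 polish
iterations — are declared, configurable choices: no published values
exist for them. Rank-linear mating was chosen over fitness-inverse
weighting because it is scale-invariant in $F$.

All randomness flows from one user seed through a named-stream splitter
(`rng_substream`), so population initialization, mating, and runt
replacement draw from independent streams and the whole pipeline is a
pure function of (configuration, seed).

## The dose engine

The engine is an analytic pencil-beam model; every part of it is a
parameterized stand-in chosen so that the *algorithmic* behaviour (depth
selectivity, lateral penumbra growth, collimation benefit) is faithful,
because no machine-specific beam data are published for the delivery
system that inspired this package:

* **Depth dose.** A Bortfeld-style power-law stopping curve convolved
  numerically with Gaussian range straggling
  $\sigma_R = 0.012\,R^{0.935}$ cm, peak-normalized; supported for ranges
  of 2–32 cm. The curve has an entrance plateau, a single peak within
  3 mm of the nominal range, and a sub-1% distal tail beyond 1 cm.
* **Lateral spread.** In-air spot sigma decreasing linearly with range
  (6 mm at $R=5$ cm to 3 mm at $R=25$ cm), added in quadrature to a
  multiple-Coulomb-scattering term $\sigma_{MCS}(d)=0.025\,R\,(d/R)^{1.7}$
  cm.
* **Collimation.** Each trimmer edge multiplies the Gaussian kernel by an
  erf-smoothed step with surface penumbra $\sigma_t = 1.1$ mm, broadened
  with depth in quadrature. Collimator scatter (and the associated
  surface-dose increase) is not modelled. A collimated profile never
  exceeds the open profile, and the sparsity cutoff (0.1% of the
  *open-field* column maximum) is shared between the two so the dominance
  survives sparsification voxelwise.
* **Geometry.** Gantry 0° enters anteriorly, angles increase toward
  patient-left, beams lie in the axial plane. Rays are marched at half
  the smallest voxel dimension; a voxel's water-equivalent depth is read
  off the central ray at the voxel's projected depth (the standard
  pencil-beam slab approximation). Entry quantization is therefore half a
  marching step (0.5 mm on the reference phantom), visible as a
  half-voxel softening of the distal edge.

## Spot and layer placement

Candidate energy layers at a control point cover the span of target WET
depths seen from that angle, on a uniform 0.5 cm grid with endpoints
rounded outward (so outward-rounded extreme layers may legitimately own
no spots). Spots sit on a 4 mm beam's-eye-view lattice aligned to the
isocentre projection, covering the target cross-section at the layer's
iso-WET surface plus a one-pitch margin implemented as axis-neighbour
dilation on the lattice; margin spots must still intersect the patient.
Cross-section membership is evaluated against target voxel centres
(within half a voxel laterally and half a voxel of water-equivalent path
longitudinally) rather than by rounding ray intersection points into
voxel indices — the latter tie-breaks asymmetrically when a lattice point
falls exactly on a voxel boundary, and mirror symmetry of the whole
pipeline is both a correctness property and a regression test here.
Trimmer edges are set per beamlet at the cross-section boundary along
each lateral axis whenever that boundary lies within $3\sigma$ of the
spot centre (sigma at the Bragg peak), else the side stays open.

## The synthetic phantoms

`reference_phantom()` is the package's study geometry: a 64 × 64 grid of
2 mm voxels forming one axial slice of a water cylinder (r = 60 mm), a
spherical target (r = 12 mm) offset 15 mm toward the patient's right, and
an abutting cylindrical organ at risk (r = 6 mm) on its medial side, with
derived structures: the 10 mm ring around the target, the 5 mm skin
shell, and the remaining "brain". The single-slice third axis is a
deliberate desk-scale choice — it preserves every mechanism the optimizer
exercises (depth selection, lateral conformity, arc geometry) at a size
where a ten-seed study is a few minutes of computation. What the phantom
does **not** emulate: heterogeneous stopping powers, patient-shaped
surfaces, three-dimensional spot grids with many rows, or the voxel
counts of a clinical CT. Passing tests on it demonstrate the optimizer's
mechanics and directional physics (collimation lowers ring dose; an arc
spreads entrance dose better than two fields), not clinical dose accuracy.

The default arc spans 140°, entering at the patient's lateral right and
wrapping posteriorly (gantry 270° down to 130°). Default objective terms
hold the target between 100% and 105% of the 50 Gy prescription, with
overdose penalties of 25 Gy on the ring, 20 Gy on the organ at risk and
12 Gy on the brain; an alternative `oar_avoidance` scenario adds a
heavily weighted 10 Gy goal to 2% of the organ at risk with the target
held between D2 ≤ 112% and D50 ≥ 96% of prescription.

## Known limitations and degenerate behaviour

* Ten independently seeded optimizations select widely different energies
  at individual control points (typically 2–6 distinct ranges among 10
  seeds) while their normalized target D95 stays within ~0.1% of the
  prescription — the energy-vs-angle assignment is strongly degenerate.
  With a 108-voxel target, however, one voxel is ~0.9% of the volume, so
  mid-curve DVH *volume* agreement between plans is limited by voxel
  granularity and by genuinely different over-prescription patterns; the
  package reports these spreads rather than hiding them.
* Weight optimization is first-order; with few iterations per generation
  the ranking reflects partially converged weights by design (fully
  converging every member every generation would change nothing
  qualitatively and cost an order of magnitude more).
* No robust (scenario-based) optimization, no delivery-time or
  energy-switching objectives, no Monte Carlo transport, no nuclear halo,
  no collimator scatter, no DICOM-RT I/O. Multi-energy (polyploid)
  control points are out of scope.

## Problem sizes used by the shipped studies

The packaged acceptance study runs ten seeds on the reference phantom at
stages = 5 (33 control points, ~1,800 cached beamlet columns shared
across seeds), population 10, 15 generations per stage — the package's
chosen desk scale for a reproducible multi-seed study. The seven-stage
schedule (129 control points) is exercised for its combinatorics; full
seven-stage dose optimization scales the same machinery by arc
resolution.
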