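---
title: "Mapping histological tissue regions onto in vivo strain fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping histological tissue regions onto in vivo strain fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`histostrain` connects two observations of the same vessel cross section
that live in different configurations: a histological section, segmented
into tissue regions in its unloaded state, and an in vivo strain field on
the loaded, pressurised vessel. This vignette documents the models behind
each stage, the tunable parameters, the numerical choices, and the limits
of what the synthetic validation can show.

## Strain estimation by direct deformation estimation

A volumetric image pair (reference and target, isotropic voxels) is
related by the affine warp

\[
W(x;p) \;=\; \begin{pmatrix} 1+p_1 & p_4 & p_7 \\ p_2 & 1+p_5 & p_8 \\
p_3 & p_6 & 1+p_9 \end{pmatrix} x + \begin{pmatrix} p_{10}\\p_{11}\\p_{12}
\end{pmatrix},
\]

fitted per window by Gauss–Newton minimisation of the summed squared
intensity differences. The deformation gradient is read off the first
nine parameters, so no displacement field is differentiated; the first
principal Green–Lagrange strain is the largest eigenvalue of
\(E = (F^\top F - I)/2\). The warp acts about the volume centre.

Numerical choices:

* **Intensity interpolation** uses prefiltered cubic B-splines (a
  tridiagonal prefilter per grid line followed by separable basis
  evaluation). Fourth-order accuracy matters here: with trilinear or
  Catmull–Rom sampling the interpolation bias propagates into the
  recovered parameters at the \(10^{-3}\) level, while cubic-spline
  sampling keeps exact affine pairs recoverable to about \(10^{-4}\) per
  parameter. A quarter-voxel clamped-stencil extrapolation band keeps
  windows fittable when their warp grazes the volume border.
* **Optimisation**: Gauss–Newton with step halving on residual increase,
  relative residual-change tolerance \(10^{-8}\), at most 200 iterations;
  windows whose reference intensity variance is below \(10^{-8}\) are
  refused (a flat window carries no deformation information).
* **Tiling** (`strain_field_from_volumes`): 16-voxel windows with 50 %
  overlap and a 6 % border margin; failed windows are masked. The
  per-window affine assumption is what the phantom two-zone test checks.

## Contour resampling and registration

Contours are stored counterclockwise as ordered point sets in µm.
Resampling fits a periodic biharmonic spline — the cubic radial basis
\(|t-t_j|^3\) with a linear tail, on a chord-length parameterisation
replicated over three periods — and evaluates it at equal parameter
spacing. Histological contours are densified to 1,000 points, in vivo
target contours to 20,000 points; at that density the nearest-point
distance to the target polyline approximates the distance to the curve to
well below the acceptance thresholds.

Non-rigid coherent point drift models the source motion as a
Gaussian-kernel-smoothed field estimated by EM. Parameters:

* `interaction_sigma` (kernel width, µm; default 150): the correlation
  length of the motion field. Calibrated on perturbed-circle phantoms so
  that lumen registrations pass the 0.2 µm RMSE gate.
* `smoothing_weight` (regularisation; default 0.2): larger values give
  smoother, stiffer motion; the suite checks that increasing it never
  roughens the displacement field.
* The mixture variance is initialised from the mean squared nearest-point
  distance after centroid superposition rather than from the classical
  all-pairs moment. On closed, pre-aligned contours the classical
  initialisation starts the annealing at the scale of the whole contour
  and produces a large, unnecessary tangential redistribution transient.
* The outlier weight is 0: both contours are clean and closed.

Multi-step registration chains CPD through auxiliary contours generated
as linear blends between the source and an equal-count, phase-aligned
resampling of the target (default fractions 1/3 and 2/3), replacing the
manually drawn intermediates of interactive workflows. Acceptance gates:
RMSE below 0.2 µm (lumen) / 0.75 µm (outer), preserved point ordering
(strictly monotone angular sequence about the centroid), and an
arc-length uniformity score (1 − CV of consecutive spacings) above 0.5.

A known limitation: CPD fixes *where the curve is*, not *which material
point goes where*. On closed, nearly featureless contours the
correspondence can slide tangentially by an appreciable fraction of the
deformation amplitude while every gate passes; the evenness requirement
actively encourages this redistribution. Downstream this is harmless for
the mapped geometry (the zero-traction solve is driven by the registered
positions), but point-wise correspondence with a known ground-truth warp
is only reproduced up to that slide.

## Meshing and the displacement–zero-traction solve

The segmented cross section is stored as shared boundary chains plus
per-region chain loops, so neighbouring regions agree exactly on their
interface. The mesher resamples each chain once (at the smaller of the
two adjacent regions' target edge lengths), fills region interiors with a
hexagonal lattice, and triangulates each region with an in-package
Bowyer–Watson Delaunay construction; elements whose centroid falls
outside the region are discarded and every boundary segment is verified
to be an element edge. Realised mean edge lengths track the target within
a few percent (the tolerance checked is 15 %).

The mapping problem prescribes the full lumen and outer boundary
displacement and applies no tractions. For such problems the interior
solution depends only weakly on the constitutive law, which is the
methodological point of the whole pipeline. The solver uses a plane
compressible Neo-Hookean energy
\(\psi = \tfrac{\mu}{2}(I_1 - 2) - \mu \ln J + \tfrac{\lambda}{2} \ln^2 J\)
with \(\mu = 2\,C_{10}\) and a plane-stress-consistent
\(\lambda = 2\mu\nu/(1-\nu)\), \(\nu = 0.45\) by default: near enough to
incompressible to emulate an incompressible reference setting while
keeping linear triangles lock-free. Any uniform scaling of \(C_{10}\)
leaves the displacement-driven solution unchanged, so the default
magnitude is irrelevant; only regional contrasts matter.

Numerics:

* **Energy-descent Newton**: the prescribed-displacement problem is the
  minimisation of the stored energy with a \(-\ln J\) barrier, so each
  iteration takes a Levenberg-damped Newton direction with an energy line
  search; near convergence, where the energy decrease falls below
  floating-point summation noise, a residual reduction is accepted
  instead. Convergence requires the free-node residual to fall below
  \(10^{-8}\) of the increment's initial out-of-balance force.
* **Continuation**: equal boundary increments (default 10) with secant
  prediction of the interior, adaptive halving, and a hard floor.
* **Updated-Lagrangian mode** (`rebase = TRUE`, used by the end-to-end
  pipeline): strongly redistributed registration displacements can excite
  local in-plane wrinkling instabilities along a total-Lagrangian path.
  Re-referencing the elements to the deformed geometry after each
  increment removes these discrete instabilities; since only the mapped
  geometry is used downstream (the solve's stresses are artificial by
  construction), this variant is equivalent for mapping purposes. On
  phantoms where both modes converge they agree to within 0.2 % of the
  boundary amplitude (checked by the suite). An automatic stabilisation spring (`stabilize`), the artificial
  damping commonly offered by commercial solvers for displacement-driven
  problems, is also available.
* Only the deformed region contours, traced along the stored boundary
  node cycles, leave this stage.

## Grouping, indices and tests

A strain voxel joins a region if its centre lies inside the region's
deformed contour (even-odd rule); boundary ties go to the smallest region
label, the `outer_excluded` region contributes nothing. No sub-voxel area
weighting is applied: at imaging resolution (40 µm voxels against
µm-scale contour features) edge effects are below the noise.

Strain distribution indices: mean, maximum, coefficient of variation
(sample SD over mean, the heterogeneity index) and the adjusted
Fisher–Pearson sample skewness (the common statistics-package default;
zero-variance samples report skewness 0 by convention, zero-mean samples
an undefined CV). Group comparisons screen both groups with Shapiro–Wilk
at the 5 % level and then run a pooled-variance t-test (both normal) or a
Wilcoxon rank-sum test — an explicit, reproducible stand-in for automatic
location-test selection. Region pairs are compared with Mann–Whitney U
tests; the Bonferroni divisor is the number of pairs actually tested
(default six: A1–A2, A1–A3, A4–A5, A1–A4, A2–A5, A3–A5), and pairs with a
missing region are skipped with a warning, mirroring sections in which
not all tissue types occur.

## The phantom module

The generator emulates the study conditions rather than any particular
animal: an annular wall with lumen diameter 1,000 µm and wall thickness
200 µm, partitioned into perturbed angular sectors with configurable area
proportions (defaults A1 0.25, A2 0.15, A3 0.15, A4 0.20, A5 0.25);
lumen and outer contours carry angular modes 2–5 of relative amplitude
3 % so that their shapes are as irregular as histological sections and
rotational correspondence is not degenerate; the boundary deformation
amplitude defaults to 40 µm (8 % of the lumen radius, a realistic
diastolic–systolic excursion).

The ground-truth interior displacement is a random combination of
closed-form equilibrium fields of homogeneous isotropic linear elasticity
on the annulus — affine fields, the Lamé fields \(x/r^2\) and
\(x^\perp/r^2\), and curl fields of harmonic stream functions
\(\mathrm{Re}(c\,z^{n})\), \(\mathrm{Re}(d\,z^{-n})\), \(n = 2, 3\) —
rescaled to the target boundary amplitude. Every component satisfies the
Navier equations for *any* Poisson ratio, so the finite-element recovery
test is well-posed: at moderate strain the nonlinear solution differs
from this field only by finite-deformation corrections. The net rotation
content is kept small (cross-configuration twist between an excised
section and the in vivo frame is not an observable the pipeline should
have to resolve).

Region-level strain defaults (A1 0.12, A2 0.055, A3 0.05, A4 0.10,
A5 0.035, noise SD 0.02, 40 µm voxels) follow the qualitative ordering of
the tissue types — highest in intact elastin without thrombus, similar in
young erythrocyte-rich thrombus, lowest in old thrombus — because no
numeric per-region levels are published; they are free parameters of the
generator.

The two-group sample generator draws AAA-like specimens from a shifted
log-normal (right-skewed, low mean, high CV) and non-AAA-like specimens
from a reflected log-normal (left-skewed, higher mean, lower CV), with
per-specimen scale jitter, plus a small common "hotspot" component
(0.2 % of samples near 0.32 strain, identical law in both groups) which
encodes the observation that peak local strains are similar in all
animals — so the maximum index is, by design, an exact null between the
groups. These families were calibrated once against that qualitative
fingerprint and then frozen.

What the phantoms do *not* emulate: ultrasound speckle and attenuation,
segmentation ambiguity of the outer wall, non-sector region topologies
(islands, layered thrombus), out-of-plane motion, and histological
processing artefacts. Passing tests therefore demonstrate the internal
consistency and material-insensitivity of the pipeline, not its accuracy
on real images.

## Sensitivity experiments

The material-insensitivity experiment meshes a phantom once, solves the
mapping with uniform stiffness and with the tissue-specific tangent-
modulus ladder (thrombus with RBCs 65 kPa, without RBCs 2.5×, elastin
10×, fragmented elastin 15×), and compares per region: the Dice overlap
of the mapped areas rasterised at 1 µm (well below any contour feature),
the absolute difference of grouped median strains in percentage points,
and the relative error with the uniform-material run — the pipeline
default — as denominator.

The segmentation-perturbation experiment rotates the internal sector
interfaces with an end-point-preserving taper, using bisection to hit a
target mean area change, then re-runs mapping and grouping. The angular
mechanism is exact and overlap-free for sector-partitioned phantoms; it
replaces generic normal offsetting, which cannot guarantee
non-intersecting regions inside an annulus.

## Problem sizes

The test-suite and acceptance runs use deliberately scaled problem sizes
chosen by the package: five phantoms at the reference geometry with mesh
edge lengths of 12.5 µm (elastin) / 25 µm (other regions) for the
sensitivity experiment (a few thousand elements per solve, a few seconds
each); registration targets of 20,000 points where the µm-level RMSE
gates are asserted; volume pairs of 28–56 voxels per axis; and 200
replicates of the 5-vs-3 group study. Mesh-refinement and
finer-discretisation checks are run on proportionally smaller vessels so
that halving the edge length remains affordable; the refinement test
shows mapped contours move by less than 0.5 µm under halving.
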