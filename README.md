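# histostrain

Vascular walls remodel heterogeneously in dissecting aneurysms: intact and
fragmented elastin, and intramural thrombus of different age, deform very
differently under physiological loading. `histostrain` implements an
analysis pipeline that relates the microstructural tissue composition of a
vessel cross section — segmented from histology in its unloaded
configuration — to the in vivo strain field of the same cross section
estimated from volumetric imaging. It is written for vascular biomechanics
researchers who want to quantify, per tissue type, the local first
principal Green–Lagrange strain `E1`.

The pipeline has five computational stages:

1. **Strain estimation.** Direct deformation estimation fits a 12-parameter
   affine warp `W(x; p)` to an image volume pair by minimising voxel
   intensity differences; the first nine parameters *are* the deformation
   gradient `F`, from which `E = (FᵀF − I)/2` and its largest eigenvalue
   `E1` follow without an intermediate displacement field.
2. **Contour registration.** Histological lumen and outer-wall contours are
   resampled with biharmonic splines and registered onto the densely
   resampled in vivo contours by non-rigid coherent point drift (CPD),
   in one or several steps through programmatically blended auxiliary
   contours. A registration is accepted only if the nearest-point RMSE is
   below 0.2 µm (lumen) / 0.75 µm (outer wall), point ordering is
   preserved, and the points are spread evenly.
3. **Region mapping.** The segmented cross section is meshed with
   region-conforming linear triangles and the registered boundary
   displacements drive a *displacement–zero-traction* solve of a plane
   compressible Neo-Hookean body: the entire boundary motion is
   prescribed, no tractions act, and the interior — in particular the
   boundaries of the tissue regions A1–A5 — is mapped into the loaded
   configuration nearly independently of the material parameters.
4. **Grouping and indices.** Strain-field values are grouped by the mapped
   region contours (voxel-centre, even-odd rule) and summarised by strain
   distribution indices: mean, maximum, coefficient of variation
   ("heterogeneity index") and skewness; groups are compared with
   normality-screened location tests, region pairs with Mann–Whitney U
   tests under Bonferroni correction.
5. **Sensitivity analysis.** The central methodological check: repeating
   the mapping with tissue-specific stiffnesses (thrombus with red blood
   cells 65 kPa; without RBCs 2.5×; elastin 10×; fragmented elastin 15×)
   and quantifying the disagreement by the Dice similarity index
   `SI = 2|A∩B|/(|A|+|B|)·100 %` and by the difference of grouped median
   strains.

Because the animal data this methodology was developed on are not
deposited, the package ships a first-class synthetic-phantom module:
annular cross sections (lumen diameter ≈ 1,000 µm) partitioned into
sector-like regions A1–A5, with a smooth nonrigid unloaded→loaded boundary
deformation whose interior continuation is known in closed form, plus
region-coded strain fields, affine-warped volume pairs, and two-group
strain-sample datasets with controlled skewness. Every stage is validated
against these ground truths.

## Worked example

```r
library(histostrain)

ph  <- generate_cross_section_phantom(phantom_geometry(), seed = 1)
ph
#> <phantom> seed=1, 5 regions, lumen diameter 1000 um, amplitude 40 um

rep <- material_sensitivity_experiment(ph, default_edge = 25, n_increments = 8)
rep
#>  region SI_percent strain_diff_pp rel_error_percent
#>      A1   99.88765     0.00000000         0.0000000
#>      A2   99.96655     0.00000000         0.0000000
#>      A3   99.70096     0.02346227         0.4112075
#>      A4   99.68166     0.02782421         0.2894417
#>      A5   99.85906     0.00000000         0.0000000
```

Each row compares the region as mapped with uniform stiffness against the
tissue-specific stiffness ladder: `SI_percent` is the Dice overlap of the
two mapped areas (100 = identical), `strain_diff_pp` the absolute
difference of the median grouped strains in percentage points of `E1`, and
`rel_error_percent` the same difference relative to the uniform-material
run. Values of SI above ~91 % and strain differences of a few hundredths
of a percentage point mean the mapping — and hence the per-tissue strain
attribution — does not depend on the assumed material.

A two-group strain-distribution study:

```r
run_group_study(n_aaa = 5, n_non_aaa = 3, seed = 1)
#> <group_study> per-index comparisons (AAA-like vs non-AAA-like):
#>   mean      branch=t    p=2.492e-06 *
#>   maximum   branch=t    p=0.7902 -
#>   cv        branch=t    p=0.0002532 *
#>   skewness  branch=t    p=0.0001005 *
```

Aneurysmal-like specimens show lower mean strain, higher heterogeneity and
right- instead of left-skewed strain distributions, while the maximum
local strain does not separate the groups — the qualitative fingerprint
the indices are designed to detect.

`run_case(case_config(seed = 1))` executes the full per-cross-section
pipeline (resample → register → gate → mesh → solve → extract → group →
statistics) on a phantom and returns a manifest with per-stage status and
metrics.

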