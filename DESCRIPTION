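Package: histostrain
Title: Mapping Histological Tissue Regions onto In Vivo Vessel Strain Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating the microstructural tissue composition of
    vessel cross sections, segmented from histology, to in vivo strain
    fields estimated from volumetric image data. Implements direct
    deformation estimation of Green-Lagrange strain from image volume
    pairs, biharmonic contour resampling, single- and multi-step
    non-rigid coherent point drift registration of unloaded histological
    contours onto loaded in vivo contours, a displacement-driven
    zero-traction plane hyperelastic finite-element solve that maps
    interior tissue-region boundaries into the loaded configuration,
    grouping of strain values by tissue region, strain-distribution
    indices with group-level hypothesis tests, and a Dice-overlap
    sensitivity analysis of the mapping's dependence on material
    parameters. A synthetic-phantom generator with known ground-truth
    deformation makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    mgcv,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr
Config/testthat/edition: 3
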