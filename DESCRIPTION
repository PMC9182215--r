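Package: qssr
Title: Quantitative Structure-Selectivity Modeling for Secondary-Sphere
    Modified Organocatalysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for multivariate structure-selectivity modeling of
    boronic-acid secondary-sphere modifiers in proline-catalyzed aldol
    reactions. Reads 3D structures (XYZ, SDF V2000) in five hypothesized
    structural configurations, computes steric and stereoelectronic
    descriptors (Sterimol L/B1/B5, distances, dihedrals, point-charge dipole
    components in the aryl-ring frame, atomic charges and charge differences,
    tabulated stretching frequencies), transforms experimental outcomes to
    log(dr) and delta-delta-G responses, searches all small descriptor
    subsets by exhaustive multivariate linear regression ranked by
    leave-one-out Q2, and compares configuration libraries per solvent.
    Ships a synthetic-data module (equicorrelated descriptor matrices,
    planted linear responses, idealized arylboronic-acid geometries,
    design-tiling outcome tables) so the whole workflow runs without
    quantum-chemistry inputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
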