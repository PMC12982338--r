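Package: axtract
Title: Tract-Embedded Axonal Strain Analysis for Brain Finite Element Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for neuroimaging-informed head impact
    simulation. Embeds diffusion-MRI tractography streamlines as chains of
    massless beam elements inside a hexahedral finite element mesh of the
    brain parenchyma, tracks axonal (fiber-axial) strain dynamically under
    arbitrary nodal displacement histories, and computes tract-level and
    global injury metrics: the enhanced tract-wise injury susceptibility
    index, the 95th-percentile peak axonal strain (AxS95), the
    95th-percentile maximum principal strain (MPS95), and the cumulative
    strain damage measure (CSDM). Includes marker-cluster strain estimation
    for cadaveric validation experiments, CORA time-history correlation
    scoring with the standard sliding rating scale, ordinal outcome rank
    correlation with exact small-sample p-values, and a synthetic fixture
    generator with closed-form strain oracles. Reads and writes TRK/TCK
    streamlines, legacy VTK and CSV meshes, and LS-DYNA keyword cards for
    per-element material axes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
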