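Package: dnarc
Title: Genetic Energy-Layer Optimization for Dynamically Collimated Proton Arc Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning toolkit for pencil beam scanning (PBS) proton arc
    therapy with optional per-beamlet dynamic collimation. Implements a
    staged genetic optimizer that assigns a single beam energy (range) to
    each gantry control point of an arc, jointly with projected-gradient
    optimization of non-negative beamlet weights under a quadratic
    dose-volume-histogram penalty objective. Includes a synthetic voxel
    phantom generator, an analytic pencil-beam dose engine (Bortfeld-style
    pristine Bragg curves, multiple-Coulomb-scattering lateral growth,
    erf-edge trimmer collimation), DVH metrics and plan reporting, and a
    seed-stability study mirroring convergence analyses used in arc-therapy
    planning research.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
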