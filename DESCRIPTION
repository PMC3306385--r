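Package: azmetrics
Title: Morphometry of Active Zone Material at Frog Neuromuscular Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometric analysis of active zone material (AZM)
    at frog neuromuscular junctions, at the scale of electron-tomographic
    reconstructions. Provides a seeded generator of synthetic three-dimensional
    active-zone scenes (presynaptic membrane, docked and undocked synaptic
    vesicles, and the beam/step/mast/rib/spar/boom/topmast/pin filament
    classes) with published class dimensions and connection statistics;
    measurement operators for filament dimensions, z-compression estimation
    and stretch correction, in-plane angles of approach, and per-vesicle
    connection counts; unit-sphere mapping and rotation-based co-alignment of
    vesicle connection sites by maximizing rib-connection overlap; and
    distance-binned connectivity profiles of undocked vesicles near vacated
    docking sites. Scenes are serialized to a versioned JSON schema and
    reports to CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, tools
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
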