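Package: qmephantom
Title: Digital Breast Phantoms and Quantitative Micro-Elastography Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of digital tissue-mimicking breast phantoms
    (multi-region invasive-ductal-carcinoma geometries and branching duct
    networks), simulation of their compression and speckle imaging with
    phase-sensitive optical coherence tomography, and quantitative
    micro-elastography (QME) reconstruction: phase-difference displacement
    estimation, weighted least-squares strain imaging, compliant-layer stress
    inversion and elasticity mapping. Includes en-face segmentation of dense
    tissue, error-function step-response analysis of boundary spatial
    resolution, and export of printable mold geometry as STL triangle meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
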