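Package: edcscore
Title: Electron-Density Compliance Scoring of Transient Protein Complex Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores rigid poses of a two-protein electron-transfer complex
    against an experimental cryo-EM density map using the electron-density
    compliance (EDC) score: the moving-average-smoothed map value averaged
    over the mobile protein's C-alpha atoms. Provides MRC/CCP4 map reading,
    3-D moving-average smoothing, nearest-voxel and trilinear point sampling,
    Kabsch least-squares superposition into a common reference frame anchored
    on the partner protein's heme, pairwise pose metrics (center-of-mass
    distance, C-alpha RMSD, Cu-Fe cofactor distance), a comparison-table
    builder, ensemble central-structure selection and spread statistics,
    trajectory-frame scoring, and a seeded synthetic-data generator
    (toy complexes, simulated Gaussian-kernel density maps, perturbed pose
    ensembles) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'edcscore-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'mrc-io.R'
    'density-map.R'
    'structures.R'
    'superpose.R'
    'metrics.R'
    'ensemble.R'
    'synthetic.R'
    'pipeline.R'
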