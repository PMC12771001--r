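Package: gitwin
Title: Patient-Specific Digital Twins of Gastrointestinal Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Synthesizes temporally varying gastrointestinal (peristaltic)
    motion on 3D anatomical volumes. Organ masks are reduced to centerlines
    by topology-preserving 3D thinning, re-expressed as tubular NURBS
    surfaces from radially cast sectional curves, and animated with an
    analytical traveling-wave contraction model. Deformed surface shells are
    voxelized into dense ground-truth displacement fields, which warp
    images, masks and dose maps into 4D sequences. Any externally produced
    deformable-registration displacement field can then be scored against
    the ground truth with geometric (target registration error, Dice,
    95th-percentile Hausdorff distance), deformation (log-Jacobian) and
    dosimetric (dose-warping error, binned RMSE) metrics. Synthetic
    curved-tube phantoms make the whole pipeline testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'gitwin-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'utils.R'
    'volio.R'
    'phantom.R'
    'centerline.R'
    'surface.R'
    'motion.R'
    'dvf.R'
    'evaluate.R'
    'pipeline.R'
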