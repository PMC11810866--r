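Package: SkinFusion
Title: Skin-Surface Segmentation and Rigid Co-Registration for
    Ultrasound-CT/MR Fusion Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markerless fusion of pre-acquired CT/MR volumes with a
    depth-camera acquisition of the patient's skin. Segments the external
    body surface from a volumetric image by slice-wise iso-value region
    growing, extracts a watertight skin mesh by marching isosurfacing of
    the binary segmentation, and rigidly co-registers the segmented skin
    against a (simulated) depth-camera surface through principal-component
    pre-alignment, a virtual-landmark translation and two-stage trimmed
    iterative-closest-point refinement. Registration quality is quantified
    with k-d-tree Hausdorff distances, per-vertex error colour maps and
    target registration error. A synthetic phantom generator produces
    CT/MR-like volumes and depth-camera surfaces with known ground-truth
    pose for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'SkinFusion-package.R'
    'mesh-io.R'
    'transform.R'
    'mesh-ops.R'
    'metaimage.R'
    'metrics.R'
    'registration.R'
    'phantom.R'
    'volume-io.R'
    'segmentation.R'
    'surface.R'
    'pipeline.R'
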