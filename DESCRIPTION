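Package: thoraxquant
Title: Radiation-Free Thoracic Volume and Spinal Length Quantification from
    Sparse Axial Chest MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-based quantification of thoracic volume and 3D
    spinal length from sparsely sampled axial chest MRI, aimed at monitoring
    chest deformation in adolescent idiopathic scoliosis without ionizing
    radiation. Provides a synthetic sparse-slice chest phantom generator with
    analytic ground truth, NIfTI input/output with anisotropic slice geometry,
    min-max normalization and model-grid resampling, a trainable 3-class 3D
    U-Net encoder-decoder with softmax voxel probabilities, nearest-neighbor
    back-resampling and 3D median-filter postprocessing, center-of-mass
    polyline spinal-length and slab-rule thoracic-volume quantification,
    spacing-aware validation metrics (Dice, Hausdorff, 95th-percentile
    Hausdorff, precision, recall, confusion overlays), and paired study
    reporting (mean/range summaries, percent differences, Cohen's dz).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
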