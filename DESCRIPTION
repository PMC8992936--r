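Package: posequiv
Title: Equivalence Evaluation of Synthetic-CT-Based Patient Positioning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end evaluation pipeline for bone-anatomy-based radiotherapy
    patient positioning with a synthetic CT (sCT) reference versus a CT
    reference, for the head-and-neck region. Provides a synthetic phantom and
    cohort generator with known ground truth; rigid 3D (6 degrees of freedom)
    and 2D orthogonal-projection (5 degrees of freedom) auto-registration with
    a mutual-information similarity metric on bone-thresholded voxels and
    downhill-simplex optimization; per-direction difference statistics and
    paired two-one-sided-tests (TOST) equivalence testing within a (-1, 1) mm
    interval; an interobserver metric based on Euclidean distances between
    planning-target-volume contour points transformed by paired registration
    matrices, with Dice overlap of the registered structures; and
    quality-assurance tools for deformable registration output
    (Jacobian-determinant fields, anatomical landmark offsets and placement
    reproducibility).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    mgcv,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
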