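Package: atrophysim
Title: Simulation of Longitudinal Brain MRI with Prescribed Volume Changes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates longitudinal brain MR images with known, voxel-wise
    prescribed volume changes (atrophy or growth).  A biophysical creep-flow
    model is solved on a staggered (MAC) finite-difference grid to obtain a
    displacement field whose divergence equals the negated prescribed atrophy
    in parenchyma while cerebrospinal fluid regions compensate freely and the
    skull stays fixed.  Simulated follow-up images are produced by pulling
    intensities through the inverse deformation with B-spline interpolation,
    optionally resampling from repeat or registered follow-up scans through
    composed deformation fields so that realistic intensity variation and
    independent acquisition noise are carried into the synthetic time series.
    Includes deformation-field calculus (divergence under face-based and
    centered stencils, Jacobian determinants, composition, fixed-point
    inversion), atrophy-map construction from ROI tables or velocity-field
    divergence, a fully deterministic brain-like phantom generator, NIfTI and
    MetaImage input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
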