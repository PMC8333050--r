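Package: AcorrTomo
Title: Inherently Aligned Multi-View Tomography by Auto-Correlation Inversion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fusion and reconstruction of multi-view light-sheet fluorescence
    acquisitions in auto-correlation space. Rotated volumetric views are fused
    by averaging their auto-correlations, which are centred in shift-space and
    therefore inherently aligned, removing the need for registration. The
    averaged auto-correlation is inverted with Schulz-Snyder fixed-point
    iterations, or simultaneously de-autocorrelated and deconvolved with the
    Anchor-Update scheme using the auto-correlation-space point-spread
    function. Includes a synthetic multi-view generator (bead, vessel-tree and
    shell phantoms blurred by angle-dependent anisotropic Gaussian PSFs), a
    cross-correlation registration baseline, PSF sharpening analysis, and
    resolution metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tiff, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
biocViews: Software, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
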