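Package: patchrefine
Title: Two-Stage Coarse-to-Fine Semantic Segmentation with
    Uncertainty-Guided Patch Refinement
Version: 0.1.0
Authors@R:
    person("patchrefine", "developers", email = "dev@patchrefine.org",
           role = c("aut", "cre"))
Description: Coarse-to-fine binary semantic segmentation: a first model
    segments a downscaled image, per-patch prediction uncertainty locates
    the regions that are hard to segment, and a second model refines only
    those patches at full resolution before the outputs are stitched back
    together.  Includes the full training recipe (focal loss, Adam,
    geometric and photometric augmentation, cross-stage weight transfer
    and penultimate-layer context fusion, per-epoch uncertainty-driven
    patch sampling), analytic parameter and multiply-accumulate
    accounting for ResNet-50-backed and tiny architectures, a seeded
    generator of cell-like synthetic images with spatially heterogeneous
    difficulty, PNM image input/output, CSV dataset manifests, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
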