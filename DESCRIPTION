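Package: holoflow
Title: Rapid 3D Localization of Cells Flowing in Off-Axis Holographic Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatiotemporal 3D particle tracking for off-axis digital
    holographic imaging flow cytometry.  Locates flowing cells
    transversely on carrier-suppressed, background-free down-sampled
    holograms (superimposed-spectrum or static-background-matching
    elimination), builds spatiotemporal tracking lines, and retrieves
    axial positions by three-step spatiotemporal phase shifting with
    angular-spectrum refocusing under the Tamura-coefficient criterion,
    avoiding frame-by-frame holographic reconstruction.  Includes a
    synthetic hologram-video simulator with exact ground truth and the
    conventional demodulate-unwrap-refocus pipeline as a reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
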