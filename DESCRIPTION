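Package: scanxray
Title: Multimodal Scanning X-ray Imaging and Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for multimodal scanning X-ray imaging and
    tomography data: streamed block-wise readout of NeXus-style HDF5 scan
    containers, pre-treatment (beam ROI and illumination-mask estimation,
    hot-pixel detection and repair, XRF energy calibration), reduction of raw
    detector frames to transmission, differential phase contrast, dark-field
    and elemental-ROI maps, intensity and geometric corrections (monitor
    normalisation, virtual-grid regridding, background referencing,
    rotation-axis and wobble estimation from sinogram centre-of-mass sine
    fits), phase integration by Fourier-derivative and Southwell least-squares
    methods, and parallel-beam tomographic reconstruction by filtered
    back-projection, ART and SIRT. Includes a synthetic acquisition forward
    model (wire and capillary phantoms) providing ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    rhdf5,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
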