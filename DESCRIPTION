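Package: dynwound
Title: Dynamic Full-Field OCT Imaging of Wound Healing in Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification of scratch-assay wound healing from dynamic
    full-field optical coherence tomography (D-FFOCT) time-lapse imaging.
    Provides the per-voxel power-spectrum "dynamic profile" renderer (hue =
    mean fluctuation frequency, saturation = inverse bandwidth, value =
    averaged running standard deviation), a semi-automatic wound
    segmentation and kinetics profiler (multi-level thresholding, rotation
    to a vertical scratch, ROI masking, per-frame area and width traces,
    wound-closure percentage, bi-exponential width kinetics with
    characteristic time and average closing speed), a Horn-Schunck optical
    flow estimator with per-front speed summaries in micrometres per hour,
    and a ground-truthed synthetic data generator for textured epithelial
    sheets with closing, retracting or expanding scratches and for raw
    interferometric bursts with controlled spectral content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
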