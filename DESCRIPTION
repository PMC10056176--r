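Package: orientfilm
Title: Orientational and Morphological Analysis of Biofilm Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital image-processing workflow for quantifying mature,
    high-coverage bacterial biofilms in stereomicroscopy images: local
    Niblack thresholding with coverage quantification, connected-component
    shape statistics (circularity, aspect ratio, Sturges-binned histograms),
    Voronoi tessellation of object centroids with a regularity index,
    per-pixel structure-tensor orientation and coherency fields (Riesz,
    Gaussian-derivative and finite-difference gradient operators), ROI-based
    directional summaries and orientation histograms, and cross-sample
    statistics (boxplot/violin summaries, Pearson/Spearman/chi-square
    comparisons, standardized PCA). A synthetic-image generator with known
    ground truth (coverage masks, per-pixel angle maps, point patterns)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
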