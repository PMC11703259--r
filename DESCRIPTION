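Package: synquant
Title: Quantification of Synaptic Protein Localization, Ultrastructure and
    Calcium Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying super-resolution (STED)
    images of cortical synapses, electron-micrograph morphometry of endocytic
    structures, and two-photon calcium line scans. Implements two-step blind
    Richardson-Lucy deconvolution with a point-spread function measured from
    non-specific antibody puncta, candidate-synapse segmentation into fixed
    regions of interest with side/top view sorting, band line-scan analysis of
    side-view synapses relative to the Bassoon/PSD95 center-line, half-maximum
    active-zone contouring with signed punctum-to-boundary distances for
    top-view synapses, parsing and morphometry of plain-text electron-micrograph
    annotations (structure counts, pit distances to the active zone along the
    membrane, pit geometry, endosome areas), and calcium dF/F0, exponential-fit
    and signal-area analysis. A fully seeded synthetic-data generator provides
    ground-truthed fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    graphics,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
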