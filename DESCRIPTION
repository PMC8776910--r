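Package: myoscore
Title: Quantification of Contractility and Protein Localization in
    EPS-Stimulated Myotube Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for feeder-supported in vitro exercise models
    of cultured human myotubes. Computes a differential-image movement index
    from bright-field time-lapse sequences of electrically paced myotubes,
    segments myotubes and nuclei from alpha-actinin/DAPI immunofluorescence
    while excluding feeder-fibroblast nuclei, scores nuclear versus
    cytoplasmic marker distribution (TDP-43-style translocation readouts),
    quantifies puncta area fractions (p62-style readouts), and derives
    relative gene expression by the 2^-deltaCt method. A ground-truthed
    synthetic-data generator emulates every input modality so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    multcomp,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
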