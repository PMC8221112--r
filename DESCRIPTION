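Package: HistoCyto
Title: HistoCytometry Analysis of Multiplex Immunofluorescence Images of
    Lymphoid Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative single-cell analysis of multispectral confocal
    images of secondary lymphoid organs in the HistoCytometry style:
    spillover compensation from single-stain controls, nuclear
    segmentation, per-cell feature extraction into a cytometry-like event
    table, hierarchical phenotype gating, microanatomical compartment
    mapping (extrafollicular space, mantle zone, germinal-center light and
    dark zones), structural area quantification, and RNAscope punctum
    detection with cell-associated versus FDC-bound classification. A
    ground-truthed synthetic tonsil/lymph-node scene simulator renders
    multichannel images (full panels and single-stain controls) with
    configurable spillover, autofluorescence and Poisson-Gaussian noise so
    that every stage of the pipeline can be validated against known cell
    phenotypes, compartment geometry and punctum placement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    mclust,
    yaml,
    tiff,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Software, SingleCell, Spatial, ImmunoOncology
RoxygenNote: 7.3.3
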