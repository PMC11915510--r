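Package: nucleoquant
Title: Quantification of Nucleolar Trafficking, DNA-Damage Foci and
    Biomolecular Condensates from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-quantification pipelines for studying nucleolar protein
    trafficking and biomolecular condensation. Provides Laplacian-of-Gaussian
    counting of nuclear DNA-damage foci, 3D segmentation of nucleolar
    fibrillar centres and dense fibrillar components with nascent-RNA (EU)
    quantification, live-cell nucleolus-to-nucleoplasm intensity-ratio
    tracking with repeated-measures ANOVA onset statistics, in vitro droplet
    condensed-fraction and partition-ratio analysis, and supporting
    biophysical utilities (NMR chemical-shift perturbation, molecule-count
    to molarity conversion, protein isoelectric point, G-quadruplex motif
    scanning). A ground-truthed synthetic microscopy generator makes every
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
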