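Package: ptcrescue
Title: Quantification Pipeline for Premature-Termination-Codon Readthrough Rescue Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify translational readthrough (TR) rescue of
    nonsense variants from dual-fluorescence reporter flow cytometry,
    stop-codon-context sequence analysis, two-channel lysosomal proximity
    imaging, 4-methylumbelliferone-calibrated enzymatic activity, and blot
    densitometry. Includes an FCS3.0 reader/writer, the scatter and
    fluorescence gating scheme and GFP/RFP ratio statistic normalized to a
    100 percent readthrough fusion control, a Phansalkar local threshold and
    erosion-marker watershed segmentation chain with object-based
    center-to-center and edge-to-edge nearest-neighbor distances, and
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
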