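Package: texdose
Title: Texture-Based Dose Readout for Polymer Gel Dosimeters from SEM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reads absorbed dose out of scanning electron microscopy (SEM)
    micrographs of irradiated polymer gel dosimeters via gray-level
    co-occurrence matrix (GLCM) texture analysis. Computes Haralick texture
    indices (entropy, contrast, energy, homogeneity) on tiled micrographs,
    rejects per-tile statistical outliers, optimizes the GLCM offset distance
    and outlier-exclusion count for dose-response linearity and sensitivity,
    fits a linear calibration curve, and inverts it to estimate absorbed dose
    in gray. Includes a synthetic generator of dose-dependent SEM-like fibrous
    textures so the full pipeline can be exercised and validated without real
    micrographs, plus a command-line interface for batch studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
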