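Package: choroidcvi
Title: Choroidal Vascularity Index from Enhanced Depth Imaging OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the choroid on enhanced depth imaging optical
    coherence tomography (EDI-OCT) B-scans. Given a grayscale B-scan and
    manually segmented layer boundaries, the package builds the 1500 um
    subfoveal choroidal region, binarizes it into luminal (dark, vascular)
    and stromal (light, interstitial) compartments with Niblack, Phansalkar
    or Otsu thresholding, and reports total choroidal area (TCA), luminal
    area (LA), stromal area (SA), the choroidal vascularity index
    (CVI = LA/TCA), the LA/SA ratio and subfoveal choroidal thickness.
    Companion tools compute per-layer thickness, volume and mean intensity
    over a raster of segmented scans, generate speckled two-compartment
    phantoms with known ground-truth luminal fraction for validation, and
    run the paired cohort statistics (Wilcoxon signed-rank, t tests,
    one-way ANOVA with R squared, percent change) used in longitudinal
    uveitis monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
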