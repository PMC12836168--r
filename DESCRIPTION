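Package: chemotaxgel
Title: Diffusion Gradients and Directed Cell Migration in 3D Collagen
    Chemotaxis Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-well collagen hydrogel chemotaxis
    chambers: characterization of tracer diffusion gradients by fitting an
    instantaneous point-source diffusion model to fluorescence line profiles,
    viscoelastic summaries from rheometer sweep tables (linear viscoelastic
    region, 1 Hz moduli, loss tangent, dynamic Young's modulus with
    propagated uncertainty), and quadrant-based quantification of directional
    stromal-cell migration toward a central tumor-cell well (rolling-ball
    background subtraction, percentile contrast enhancement, a pixel
    classifier producing probability maps, Yen automatic thresholding, and a
    permutation test for directional bias). A synthetic-data module generates
    tracer stacks, agent-based chemotactic migration movies, and confluency
    images with known ground truth so every stage is testable without raw
    microscopy.
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
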