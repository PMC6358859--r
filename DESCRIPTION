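Package: poreload
Title: Substance Distribution Analysis in Porous Microparticle Drug Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how loaded substances distribute inside porous
    microparticle drug carriers such as functionalized calcium carbonate.
    Combines interpretation of mercury intrusion porosimetry (Young-Laplace
    pressure-to-diameter conversion, pore size distributions, tablet
    porosity) with cross-section image analysis (wavelet-FFT curtaining
    removal, FFT bandpass flattening, SLIC superpixel segmentation,
    equivalent-sphere pore metrics), thermogravimetric two-component content
    deconvolution, and Washburn capillary-rise contact angles. A synthetic
    pore-network generator with an ink-bottle percolation simulator provides
    ground truth for validating the discrimination of open, filled, and
    blocked pores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
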