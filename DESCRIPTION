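Package: mycospec
Title: Chemometric Assessment of Filamentous Fungal Biomass from
    FT-Raman and FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative assessment of filamentous fungal
    biomass composition from vibrational spectra. Implements the standard
    chemometric workflow used in high-throughput fungal screening:
    Savitzky-Golay smoothing and derivatives, rubber-band (convex hull)
    baseline correction, extended multiplicative signal correction (EMSC),
    region truncation, technical-replicate quality control by Pearson
    correlation, principal component analysis and multiblock consensus PCA,
    partial least squares regression calibration of total lipids, total
    phosphorus and carotenoids with bioreplicate-held-out validation,
    Raman band-intensity ratio screening, and ANOVA-model decomposition of
    spectral variance over a factorial cultivation design. A synthetic
    spectrum generator emulates a six-strain Mucoromycota cultivation
    design with band structure, multiplicative scatter, baseline drift,
    laser-heating artifacts and noise, providing ground truth for
    validating the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
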