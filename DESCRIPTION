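Package: mtmorph
Title: Morphometry of Centrilobular Fibrosis and Sinusoidal Lumens in
    Masson's Trichrome Liver Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic quantification of centrilobular fibrosis and
    sinusoidal lumen area in Masson's-trichrome-stained liver regions of
    interest. Implements HSB (hue-saturation-brightness) box thresholding on
    the 0-255 integer scale with fixed, empirically established bands for
    collagen and for black-filled sinusoidal lumens, centrilobular-vein
    exclusion by white fill, 3x3 mean smoothing, physical-area measurement
    from a micrometre-per-pixel calibration, the centrilobular fibrosis
    ratio (CFR) and sinusoidal lumen ratio (SLR), per-slide aggregation, and
    a deterministic batch engine writing CSV results. Ships a synthetic
    histology phantom generator with exact ground-truth masks for
    end-to-end validation, and a cohort statistics layer (score
    frequencies, group summaries, normality checks, one-way ANOVA with
    Tukey post-hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
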