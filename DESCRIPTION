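Package: tinnscreen
Title: Conditioned-Suppression Tinnitus Assessment and Immunoreactivity
    Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for animal-model tinnitus studies built
    on operant conditioned suppression. Provides a seeded generative model of
    60-minute lever-press sessions with embedded probe periods under a latent
    tinnitus-severity parameter, the running suppression-ratio statistic
    R = B/(A+B) with per-minute epoching and session quality-control
    criteria, psychophysical discrimination functions, the prominent/weak
    tinnitus subgroup classification rule, mixed-design ANOVA group
    comparison, DAB micrograph percent-area immunoreactivity quantification
    (AOI-restricted thresholding and 8-connected particle analysis) with a
    ground-truth synthetic micrograph generator, and a relative
    diffusion-coefficient estimate from molecular weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    withr,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization, QualityControl
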