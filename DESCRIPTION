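Package: sstmorph
Title: 3D Morphometry of Avian Sperm Storage Tubules from Light-Sheet Volumes
Version: 0.1.0
Authors@R:
    person("UVJ", "Morphometry Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for cross-sectional morphometry of
    avian sperm storage tubules (SSTs) imaged by selective plane illumination
    microscopy (light-sheet). Two side traces of a tubule are averaged into a
    luminal centerline, parameterized by arc length, and sampled at equidistant
    points; oblique image sections normal to the local tube direction are
    extracted from the 3D stack by trilinear interpolation; major and minor
    axis diameters, circularity, and mean diameter are measured on each
    section via moment-equivalent ellipses; and linear mixed-effects models
    (random intercept per bird, Satterthwaite inference, Nakagawa-Schielzeth
    marginal/conditional r-squared) describe the diameter profile and
    ellipticity along the tubule. A synthetic-data module renders SPIM-like
    volumes of tubules with punctate epithelial autofluorescence and known
    ground-truth geometry so every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
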