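Package: soundsoil
Title: Soil Soundscape Analysis and Acoustic Biodiversity Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring of soil fauna: computes an
    averaged Acoustic Complexity Index (ACI) from belowground audio
    recordings, fits hierarchical Bayesian gamma regression models with an
    autoregressive error structure to ACI time series (daytime/season and
    microclimate predictors, scenario predictions with highest density
    intervals), quantifies soil community diversity with Hill numbers,
    ordination (NMDS on Bray-Curtis distances) and stratified PERMANOVA, and
    links acoustic complexity to community attributes through linear mixed
    models at several temporal resolutions. Includes a seeded synthetic
    soundscape, microclimate and community generator so the full pipeline can
    be exercised and validated without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    nlme,
    vegan,
    rjags,
    coda,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
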