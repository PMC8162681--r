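Package: aqrep
Title: Population-Health Based Representativeness of Air Quality
    Monitoring Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates how well a fixed-site air quality monitoring network
    represents the short-term health risks of a city's population. Hourly
    gridded concentration fields of PM10, PM2.5, NO2 and O3 are transformed
    into additive excess hospital-admission risks (%AR) via an exponential
    concentration-response model, compared cell-by-cell against the grid
    cells holding the monitors (pseudo-stations) with the similarity
    frequency (SF) method, and aggregated into a population-weighted
    network representation index (PHNI) at annual, seasonal and district
    scales. Includes rasterization of irregular dispersion-model output
    meshes, nearest-neighbour population resampling, model-verification
    statistics (index of agreement, RMSE), and a seeded synthetic scenario
    generator for fully reproducible end-to-end analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    mgcv,
    jsonlite,
    yaml,
    rlang,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
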