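Package: seagrassmapr
Title: Shallow-Water Benthic Habitat Mapping and Seagrass Change Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for interannual seagrass change detection from
    multispectral coastal imagery: conversion of at-water-surface reflectance
    to remote-sensing reflectance, band log-ratio satellite-derived bathymetry,
    analytical water-column correction for optically shallow water, random-forest
    benthic classification (Cymodocea nodosa, Posidonia oceanica, rocky algae,
    sand), error-matrix accuracy assessment (overall, producer, user, kappa),
    and per-class area, trend, and gain/no-change/loss change detection.
    Includes a synthetic-scene generator built on the same forward radiative
    model so every stage is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
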