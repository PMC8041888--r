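Package: tofscape
Title: Mapping Trees Outside Forests from Fused Optical and Radar Imagery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for national-scale accounting of trees outside
    forests (TOF). Fuses multi-date optical (NDVI) and dual-polarization
    C-band radar (VH/VV backscatter) composites into a tree-extent mask via
    threshold windows, a forest exclusion mask and a minimum-patch sieve;
    labels patches and summarises their size distribution; interpolates a
    bare-earth terrain model from ground control points by inverse-distance
    weighting and differences it from a surface model to obtain canopy
    height; calibrates heights against a reference canopy surface in 1-ha
    plots with outlier screening, a minimum-height rule and a per-division
    percentile cap; and produces stratified accuracy and area estimates with
    95% confidence intervals. Includes a synthetic-scene generator with known
    truth so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
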