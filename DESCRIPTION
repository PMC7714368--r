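Package: nratool
Title: National Responsibility and Conservation Priority Assessment for
    Species Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines national responsibilities and conservation priorities
    for species from polygon overlays of distribution ranges, biogeographical
    units, focal (administrative) areas and a reference area. Computes expected
    and observed distribution proportions, classifies distribution patterns as
    local, regional or wide by either a polygon-count or a polygon-area
    approach, applies a decision tree to assign national-responsibility
    classes, and crosses these with global IUCN Red List categories to obtain
    conservation-priority classes and scores. Includes GeoJSON vector input
    and output, dBase and CSV attribute tables, an ASCII run summary, a
    deterministic synthetic toy-world generator with analytically known areas,
    a rasterized area oracle for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    foreign,
    geosphere,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
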