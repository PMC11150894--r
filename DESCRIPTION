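Package: geomask
Title: Pinwheel Point Obfuscation with Census-Region Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for geographic masking of patient-level point data.
    Implements pinwheel point obfuscation, in which displacement distance is
    a sawtooth function of a random azimuth, and a geographically
    constrained variant that rejection-samples candidates until the masked
    point stays inside a designated census region, so that region-linked
    attributes (e.g. tract poverty rates) are preserved exactly. Includes
    census GEOID hierarchy handling and point-in-region assignment, audit
    procedures quantifying region shifts and neighborhood poverty-rate
    misclassification caused by unconstrained masking, Getis-Ord Gi*
    hotspot analysis on region-aggregated counts, and a synthetic
    nested-tessellation generator so the whole pipeline is testable without
    external census downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
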