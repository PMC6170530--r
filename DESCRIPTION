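Package: ccdeval
Title: Coupling Coordination Degree Assessment of Soil-Vegetation Systems
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Composite-index evaluation of paired ecological systems using
    the coupling coordination degree (CCD) model. Raw plot-by-indicator
    survey matrices are min-max normalized over a hierarchical indicator
    system (system, subsystem, indicator), weighted by a combined scheme
    (analytic hierarchy process weights for subsystems times entropy
    weights for indicators), aggregated into per-plot comprehensive scores,
    and scored for coupling degree, coupling coordination degree and lag
    diagnosis, with band-based coordination classification. Includes a
    synthetic-data generator that inverts the normalization so pipelines
    can be tested against known ground-truth scores, plus a command-line
    interface for running assessments on CSV/YAML inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
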