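Package: hullrange
Title: Time-Scaled Local Convex Hull Home Ranges for Central-Place Foragers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-scale home-range analysis of GPS-tracked central-place
    foragers. Quality-filters raw GPS fix tables, decodes a two-state
    (travel versus area-restricted search) hidden Markov model on travel
    rate, builds time-scaled local convex hull (T-LoCoH style) hullsets
    with fixed-k and adaptive-a neighbour selection, derives 95% isopleth
    home ranges and 30% visitation-sorted core areas, computes per-hull
    revisitation and residency metrics with a six-category behavioural
    classification, and provides an AICc multimodel-inference layer for
    linear mixed-effects candidate sets. Includes a seeded simulator of
    central-place foraging tracks with ground-truth behaviour labels for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    lme4,
    polyclip,
    sp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
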