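Package: accessfca
Title: Spatial Accessibility of Community Care Facilities via Floating
    Catchment and Potential Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the spatial accessibility of community care
    facilities for elderly residents at sub-district scale. Implements the
    two-step floating catchment area (2SFCA) method, the potential
    (gravity) model with a distance-decay friction coefficient, and a
    two-step gravity variant with attenuated supply-demand ratios, all
    expressed through one kernel-weight abstraction. Includes equal-interval
    choropleth classification, percentile band assignment across model runs,
    facility-planning prioritization, summary reporting against a
    beds-per-elderly policy threshold, and a seeded synthetic region
    generator emulating a dense urban study area with community demand
    polygons and facility bed counts.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
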