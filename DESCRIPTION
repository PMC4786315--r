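Package: nomadsim
Title: Agent-Based Simulation of Mobile Pastoralism on Satellite-Derived
    Resource Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates mobile pastoralist agents ("NOMADs") that follow and
    adaptively update cyclic yearly routes of twelve monthly camping sites on
    a gridded dryland environment whose per-site, per-month grazing resources
    are derived from monthly vegetation-index (NDVI) rasters.  Agents gather
    information by grazing and scouting, remember per-site per-month time-mean
    availability, and select new routes by a softmax rule over a route
    potential (negative remembered resources plus movement costs) with
    annealing-style state-dependent noise.  The package includes resource
    sharing and yearly carrying-capacity bookkeeping, tsetse-fly disruption
    and cropland access-schedule extensions, a synthetic-environment generator
    for fully offline testing, and a land-use analysis layer (monthly
    intensity maps, seasonal classification, confusion matrices and Cohen's
    kappa, route range and resource summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
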