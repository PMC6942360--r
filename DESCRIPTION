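Package: spomdyn
Title: Stochastic Patch Occupancy Models in Dynamic, Successional Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-species metapopulation occupancy with the
    Incidence Function Model (IFM) on randomly generated patch networks
    subject to patch turnover (disturbance) and habitat succession. Patch
    age modifies extinction and colonization probabilities according to a
    species' successional preference (early, mid or late), so the package
    can test the metapopulation intermediate-disturbance hypothesis: does
    equilibrium occupancy peak at intermediate patch-turnover rates?
    Provides a landscape generator (random circular patches with a minimum
    inter-patch spacing, per-step destruction and creation of a fixed
    fraction of patches), a factorial virtual-species set, trajectory
    simulation, a factorial experiment runner with per-iteration seeding,
    and figures of occupancy versus landscape dynamism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
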