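Package: dietshift
Title: Diet Clusters, Environmental Footprints and Dietary Transition Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links food-frequency dietary intake data to multi-indicator
    environmental footprints and diet quality. Computes per-person life-cycle
    impacts (global warming potential, land use, marine and freshwater
    eutrophication) from ingredient-level intakes and per-gram characterization
    factors, adapts impact factors to a target country by trade-based
    electricity-mix and feed-origin substitution, scores overall diet quality
    with a modified Baltic Sea Diet Score, identifies self-selected diet
    clusters by survey-weighted multiple factor analysis followed by Ward
    hierarchical clustering with k-means consolidation, characterizes clusters
    with v-tests and non-parametric post-hoc tests, and quantifies
    dietary-transition scenarios. A synthetic-population generator with planted
    cluster structure makes every stage testable without access-restricted
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
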