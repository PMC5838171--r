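Package: mspfrontier
Title: Multi-Sector Marine Spatial Planning Tradeoff Analysis for Offshore Aquaculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analytical engine for coordinated marine spatial planning of
    offshore aquaculture. Builds per-site sector response and scaled value
    tensors for gain sectors (mussel, finfish, kelp aquaculture; a wild-capture
    fishery) and impact sectors (viewshed, benthic health, disease risk via
    eigenvector centrality of a hydrodynamic connectivity matrix), derives
    exact optimal siting plans by per-site weighted argmax across a full grid
    of sector priority weights (the efficiency frontier), simulates
    conventional-planning counterfactuals from a suitability index, measures
    the value of coordinated planning against them, and distills planning
    products: filtered plan sets, development hotspot maps, and
    cluster-derived seed plans via Bray-Curtis dissimilarity, single-linkage
    clustering and non-metric multidimensional scaling. Includes a synthetic
    seascape generator so the whole pipeline runs without external data, plus
    discounted cash-flow economics (net present value and equivalent annual
    annuity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
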