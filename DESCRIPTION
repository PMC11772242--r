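Package: glcm
Title: Global Landed Cost Modelling for Traded Grain Commodities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds field-to-customer landed costs for internationally traded
    grain and oilseed commodities. Converts per-hectare farm input costs into
    regional per-tonne production costs, routes freight over a five-layer
    multimodal transport network with a generalized-cost Dijkstra search,
    downscales bilateral trade to subnational region pairs with a radiation
    spatial-interaction model, and aggregates the resulting flows into
    weighted landed-cost statistics (supply cost curves, inequality of
    sourcing costs). Two scenario engines cover static input-price-shock
    pass-through with driver attribution and cost-reduction benchmarking
    with k-means strategy typologies. A deterministic synthetic-world
    generator provides complete, internally consistent input bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
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
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
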