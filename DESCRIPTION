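Package: centrobust
Title: Robustness of Network Centrality Rankings Under Biased Edge Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates six biased edge-removal (down-sampling) schemes on
    undirected networks and quantifies how each distorts node-centrality
    rankings. Provides synthetic network generators (Erdos-Renyi,
    Barabasi-Albert, Watts-Strogatz), six centrality measures tolerant of
    disconnected graphs, a replicated Spearman rank-correlation robustness
    protocol over a grid of removal fractions, and a rank-variability
    stability analysis that flags nodes whose centrality rank stays
    consistent across perturbation levels. Results are tidy tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() visuals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
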