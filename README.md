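# centrobust

Network centrality is routinely computed on incompletely observed graphs:
protein-interaction maps miss interactions, metabolic and regulatory
networks carry curation gaps, and which edges are missing is rarely random
— detection effort concentrates on hubs, on well-studied pathways, or on
whatever a random walk of experimental attention happened to visit.
**centrobust** quantifies what this does to centrality *rankings*. It
treats a known graph as ground truth, removes a chosen fraction of its
edges under one of six biased sampling schemes, and measures how far each
of six centrality rankings drifts from the intact ranking. It is aimed at
systems biologists and network scientists who want to know how much trust
a centrality-based prioritisation deserves under observational error.

## The model

Let `G = (V, E)` be a simple undirected graph. Each removal scheme defines
a probability distribution over edges, normalised so `Σ_e P(e) = 1`:

| scheme | raw weight of edge `e_uv` | bias |
|---|---|---|
| RER   | `1` | none (uniform) |
| HCER  | `deg(u) + deg(v)` | strips hubs |
| LCER  | `p(u) + p(v)`, `p(v) = max_deg − deg(v) + 1` | strips the periphery |
| CER   | `h(deg u) + h(deg v)`, `h(x) = 1 / (1 + |x − mean(deg)|)` | strips mid-degree nodes (see vignette) |
| RNBER | `r(u)·r(v)`, `r(v) ~ Uniform(0,1)` per node | random node-level |
| RWER  | `PR(u) + PR(v)` (PageRank, damping 0.85) | random-walk attention |

A removal run draws `round(f·|E|)` edges without replacement with
probabilities proportional to these weights, deletes them (keeping all
nodes), recomputes a centrality measure — degree, betweenness, closeness,
eigenvector, PageRank or subgraph centrality — and reports the Spearman
rank correlation ρ between intact and reduced rankings. The protocol
repeats this over a grid of fractions (10%…90%) with 10 replicates and
averages ρ per cell. A companion stability analysis ranks every node at
each removal level, takes the standard deviation of its rank across
levels, and flags nodes strictly below the 25th percentile of those
standard deviations as *stable*.

## Worked example

```r
library(centrobust)

g <- generate_barabasi_albert(500, 5, seed = 1)
graph_summary(g, id = "ba_demo")
#> # A tibble: 1 × 5
#>   network nodes edges mean_degree max_degree
#> 1 ba_demo   500  2475         9.9        108

curve <- robustness_curve(g, method = "lcer", measure = "pagerank",
                          fractions = seq(0.1, 0.9, by = 0.2),
                          replicates = 10, master_seed = 42,
                          network_id = "ba_demo")
tidy(curve)
#> # A tibble: 5 × 7
#>   network method measure  fraction mean_rho  sd_rho n_rho
#> 1 ba_demo lcer   pagerank      0.1    0.938 0.00596    10
#> 2 ba_demo lcer   pagerank      0.3    0.846 0.0143     10
#> 3 ba_demo lcer   pagerank      0.5    0.734 0.0212     10
#> 4 ba_demo lcer   pagerank      0.7    0.603 0.0179     10
#> 5 ba_demo lcer   pagerank      0.9    0.407 0.0277     10
autoplot(curve)   # mean ρ vs fraction removed, ±1 sd ribbon
```

Even under the gentlest biased scheme (LCER), removing half the edges of
this scale-free graph already drops the PageRank ranking to ρ ≈ 0.73
against the truth; at 90% removal barely the top of the ranking survives.
The stability pipeline asks a different question — *which* nodes keep
their rank:

```r
prof <- stability_profile(g, method = "lcer", measure = "pagerank",
                          levels = seq(0.1, 0.9, by = 0.1), master_seed = 42)
glance(prof)
#> # A tibble: 1 × 7
#>   method measure  threshold percentile n_nodes n_stable pct_stable
#> 1 lcer   pagerank      71.5       0.25     500      125         25
head(stable_nodes(prof))
#> [1] "v1"   "v10"  "v101" "v103" "v105" "v106"
autoplot(prof)    # mean rank vs rank variability, stable nodes highlighted
```

The threshold 71.5 is the 25th percentile of the per-node rank standard
deviations; by construction about 25% of nodes are flagged stable when
the deviations are distinct — the interesting output is *which* ones.

Full experiments (networks × schemes × measures × fractions ×
replicates) run from a YAML config or a preset via `run_experiment()`,
which writes tidy CSVs and a manifest; `paper_preset("synthetic_full")`
is the nine-network benchmark configuration. A thin CLI wrapper lives at
`inst/cli/centrobust.R`.

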