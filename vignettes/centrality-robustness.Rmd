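---
title: "Centrality robustness under biased edge sampling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality robustness under biased edge sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrobust)
```

## The problem

Observed networks are samples of true networks, and the sampling is
biased: interactions involving well-studied hub proteins are
over-reported, peripheral interactions under-reported, and whole regions
of a network can be dark simply because no assay has visited them. Any
statistic computed on the observed graph — here, node centrality
rankings — inherits that bias. centrobust makes the bias explicit: start
from a graph taken as ground truth, delete a controlled fraction of
edges under a named bias model, and measure the damage to each
centrality ranking.

## The six removal schemes

Each scheme is a probability distribution over the current edge set.
Writing `deg(v)` for degree and normalising all raw weights to sum to 1:

- **RER** (random): `P(e) = 1/|E|`. The unbiased baseline.
- **HCER** (highly connected): raw weight `deg(u) + deg(v)`. Models
  over-pruning of hub edges, e.g. promiscuous binders being flagged as
  false positives.
- **LCER** (lowly connected): node score `p(v) = max_deg − deg(v) + 1`,
  raw weight `p(u) + p(v)`. Models overlooked peripheral interactions.
  The score is our closed form for "inverse degree adjusted by the
  maximum degree"; the `+1` keeps edges between two maximum-degree nodes
  at nonzero weight, so the distribution's support is always the full
  edge set and mirrors HCER's additive structure.
- **CER** (combined): `h(x) = 1/(1 + |x − mean(deg)|)`, raw weight
  `h(deg(u)) + h(deg(v))`. As written, `h` is *largest at the mean
  degree*, so this removes edges at mid-range nodes and spares the
  extremes. A described intent of such a scheme — targeting both tails
  of the degree distribution while avoiding mid-range nodes — is the
  opposite weighting; we expose it as `cer_invert = TRUE`, which uses
  `1 − h`. The package default is the literal formula. The choice
  matters: on scale-free graphs the inverted variant preserves rankings
  far better at high removal fractions (the mid-degree bulk, i.e. most
  nodes, keeps its edges), and the package's own tests compute this
  comparison (`robustness_run(..., cer_invert = TRUE/FALSE)` on a
  BA graph at 90% removal).
- **RNBER**: each node draws `r(v) ~ Uniform(0,1)` once per removal run;
  raw edge weight `r(u)·r(v)`. Node-level noise with no structural bias
  in expectation.
- **RWER**: raw weight `PR(u) + PR(v)` with PageRank on the undirected
  graph, damping 0.85 (the conventional default; tolerance 1e-10).
  Models attention spreading along chains of study.

On any regular graph all degree- and PageRank-derived schemes collapse
to the uniform distribution — a symmetry the test suite asserts.

## Sampling without replacement

A removal run deletes `round(f·|E|)` edges (round half to even, so
`f = 0` removes nothing and `f = 1` empties the graph). The contract is
the sequential conditional distribution: draw one edge with probability
proportional to its weight, renormalise over the survivors, repeat. We
realise it with exponential race keys (`Exp(1)/w(e)`, remove the
smallest), which is distributionally identical and `O(|E| log |E|)`;
the equivalence is checked against brute-force enumeration of all
ordered draws on a 4-edge fixture.

Weights are **static** by default: computed once on the intact graph and
used for the whole draw. No recomputation rule is part of the scheme
definitions, and static weights make runs reproducible and cheap. An
`every-k` policy (recompute on the residual graph every `k` removals) is
available for sensitivity analysis; with `refresh_k = 1` it is the fully
adaptive variant.

## Centrality conventions

Removal runs routinely disconnect graphs, so every measure must be
defined on disconnected input and return a score for *every* node:

- **degree** — raw incident-edge count (normalisation by `n − 1` is
  rank-preserving, so raw counts change nothing downstream).
- **betweenness** — exact Brandes, normalised by `(n−1)(n−2)/2`,
  endpoints excluded.
- **closeness** — Wasserman–Faust generalisation: with `R` reachable
  others at total distance `S`, closeness is `(R/(n−1))·(R/S)`;
  isolated nodes score 0.
- **eigenvector** — principal eigenvector of the adjacency matrix
  (ARPACK), nonnegative, L2-normalised; nodes outside the dominant
  component receive numerically zero scores.
- **PageRank** — damping 0.85, uniform teleport over all nodes, so
  isolated nodes retain teleport mass and scores sum to 1.
- **subgraph** — the diagonal of `exp(A)` via dense symmetric
  eigendecomposition `Σ_i u_iv² e^{λ_i}`; `O(n³)`, intended for graphs
  up to a few thousand nodes. When `λ_max > 700`, `e^{λ_max}` overflows
  double precision; the vector is then scaled by `e^{−λ_max}`, which is
  rank-preserving and flagged in the result's `scaled` attribute. An
  isolated node scores exactly 1 (the identity walk).

Ranks are descending (1 = most central) with average ties, so rank sums
are always `n(n+1)/2` and Spearman's ρ is literally the Pearson
correlation of the rank vectors. When a ranking is constant (e.g. all
scores zero after extreme removal) ρ is undefined and recorded as
missing — averaging in a fabricated 0 would bias curves downward.

## The robustness protocol

For each (network, scheme, measure, fraction, replicate): draw a removal
set **from the intact graph** (fresh-draw semantics), delete it, compute
the measure on intact and reduced graphs over the identical node set,
record ρ. Fractions are independent draws rather than nested deletions —
the removal-percentage grid enumerates fractions of the *original* edge
set, and fresh draws keep fractions statistically exchangeable across
replicates. A `cumulative = TRUE` mode provides the nested reading for
comparison. Default grid 0.1–0.9 by 0.1, 10 replicates, matching the
benchmark protocol.

Every cell's RNG seed is a deterministic hash of (master seed, network
id, scheme, fraction index, replicate index) — MINSTD-style rolling hash
mod `2³¹ − 1` — so any single cell can be recomputed in isolation and a
whole run is bit-reproducible. The seed does not include the measure:
all six measures score the *same* reduced graph, which is both the
cheaper and the more coherent reading of "recalculate the centrality"
per draw.

## The stability analysis

For one (scheme, measure): rank all nodes on one sampled reduced graph
per removal level (default 0.1–0.9; the intact ranking is *not* a
column, matching the 10–90% framing), take each node's rank standard
deviation across levels, threshold at the 25th percentile of those
standard deviations (linear interpolation between order statistics), and
flag nodes *strictly below* the threshold as stable. One draw per level
is the default; replicate-averaged ranks can be emulated by averaging
`rank_trajectories()` outputs. With distinct standard deviations and the
full node set as denominator the stable fraction is ~25% by
construction (±1/|V|) — the informative output is which nodes are
flagged, and how the set shifts across schemes. A node-subset file can
restrict the denominator (e.g. to a curated core set), which is the only
way cells far from 25% arise without heavy ties.

## Problem sizes and defaults

The package's own test suite and acceptance script run the protocol at
the benchmark scale for the synthetic families (n = 1000; ER p = 0.1,
BA m ∈ {50, 110, 500}) with 10 replicates for the single-network claims
and 5 for the three-density scale-free sweep, and at n = 200–500 for
property-style checks. BA attachment counts are integers recovered from
the benchmark edge counts via `|E| = m(n−m)` (printed densities 0.1/
0.2/0.5 map to m = 50/110/500); WS ring degrees k ∈ {100, 200, 500}
are recovered via `|E| = nk/2`. ER realisations are validated
distributionally (binomial mean/variance), not against any single
realisation's edge count.

## What the generators do and do not emulate

The synthetic families reproduce the degree structure that drives the
schemes: Poissonian homogeneity (ER), power-law hubs (BA), and locally
clustered near-regularity (WS). They do not emulate degree-degree
correlations, modularity, or the bipartite-projection artefacts of real
interactome pipelines, so a passing benchmark here bounds what biased
sampling does to *topology-driven* rank drift, not every bias a real
screen can produce. Biological network files can be supplied as
edge-list TSV or GraphML and run through the identical pipeline;
directed inputs are symmetrised, duplicate edges collapsed, self-loops
dropped.

## Known limitations

- Subgraph centrality's dense eigendecomposition makes n ≳ 5000
  impractical; there is no sparse approximation in the package.
- The literal CER weighting and its inverted variant bracket the
  scheme's ambiguity (see above); we make no claim about which matches
  any particular published run.
- Undefined correlations at extreme removal are reported as missing and
  excluded from means; per-cell counts of usable replicates are part of
  every summary (`n_rho`), and conclusions at 90% removal should check
  them.
- Edge *addition* (spurious-edge error) is not modelled; the schemes
  only remove.
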