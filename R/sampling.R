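#' Edge-removal probability distributions
#'
#' The six biased down-sampling schemes assign every edge a removal weight,
#' normalised to sum to one over the current edge set:
#'
#' * **rer** — uniform, `P(e) = 1/|E|`.
#' * **hcer** — degree-sum weighting, raw weight `deg(u) + deg(v)`; edges at
#'   hubs are removed preferentially.
#' * **lcer** — inverse-degree weighting via node score
#'   `p(v) = max_deg - deg(v) + 1`, raw edge weight `p(u) + p(v)`; edges at
#'   poorly connected nodes are removed preferentially. The `+1` keeps
#'   maximum-degree endpoints at nonzero weight.
#' * **cer** — mean-degree-distance weighting,
#'   `h(x) = 1 / (1 + |x - mean(deg)|)`, raw weight
#'   `h(deg(u)) + h(deg(v))`; with `cer_invert = TRUE` the complement
#'   `1 - h` is used instead, targeting degree-distribution extremes.
#' * **rnber** — each node draws `r(v) ~ Uniform(0,1)` once; raw edge weight
#'   `r(u) * r(v)`.
#' * **rwer** — PageRank-sum weighting, raw weight `PR(u) + PR(v)` with
#'   PageRank computed on the undirected graph (damping `damping`).
#'
#' `edge_weights()` dispatches on `method`; the `weights_*()` functions are
#' the individual schemes. On any regular graph every scheme reduces to the
#' uniform distribution.
#'
#' @param g Undirected simple graph.
#' @param method One of `"rer"`, `"hcer"`, `"lcer"`, `"cer"`, `"rnber"`,
#'   `"rwer"` (case-insensitive).
#' @param rnber_values Optional named numeric vector of per-node values for
#'   the rnber scheme (one per node); by default drawn from the current RNG
#'   state. Injectable for reproducibility and testing.
#' @param damping PageRank damping factor for rwer, in (0, 1).
#' @param cer_invert Use `1 - h` distance weighting for cer (see above).
#' @return A tibble with columns `from`, `to`, `weight` (summing to 1),
#'   of class `edge_removal_distribution`, carrying the scheme tag and the
#'   node-score map in attributes `scheme` and `node_weights`.
#' @examples
#' edge_weights(toy_fixture("kite"), "hcer")
#' @export
edge_weights <- function(g, method, rnber_values = NULL, damping = 0.85,
                         cer_invert = FALSE) {
  method <- tolower(method)
  switch(method,
    rer   = weights_rer(g),
    hcer  = weights_hcer(g),
    lcer  = weights_lcer(g),
    cer   = weights_cer(g, invert = cer_invert),
    rnber = weights_rnber(g, values = rnber_values),
    rwer  = weights_rwer(g, damping = damping),
    abort(sprintf("unknown removal method '%s'.", method))
  )
}

#' @export
removal_methods <- function() c("rer", "hcer", "lcer", "cer", "rnber", "rwer")

new_removal_distribution <- function(g, raw, scheme, node_weights = NULL) {
  check_nonempty_edges(g)
  if (any(!is.finite(raw)) || any(raw < 0)) {
    abort(sprintf("%s produced non-finite or negative raw weights.", scheme))
  }
  total <- sum(raw)
  w <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  out <- edge_tibble(g)
  out$weight <- unname(w)
  structure(
    as_tibble(out),
    scheme = scheme,
    node_weights = node_weights,
    class = c("edge_removal_distribution", class(as_tibble(out)))
  )
}

#' @rdname edge_weights
#' @export
weights_rer <- function(g) {
  check_graph(g); check_nonempty_edges(g)
  new_removal_distribution(g, rep(1, igraph::ecount(g)), "rer")
}

endpoint_sum_weights <- function(g, score) {
  el <- igraph::as_edgelist(g, names = FALSE)
  score[el[, 1]] + score[el[, 2]]
}

#' @rdname edge_weights
#' @export
weights_hcer <- function(g) {
  check_graph(g); check_nonempty_edges(g)
  p <- igraph::degree(g)
  nw <- stats::setNames(as.numeric(p), node_names(g))
  new_removal_distribution(g, endpoint_sum_weights(g, p), "hcer", nw)
}

#' @rdname edge_weights
#' @export
weights_lcer <- function(g) {
  check_graph(g); check_nonempty_edges(g)
  deg <- igraph::degree(g)
  p <- max(deg) - deg + 1
  nw <- stats::setNames(as.numeric(p), node_names(g))
  new_removal_distribution(g, endpoint_sum_weights(g, p), "lcer", nw)
}

#' @rdname edge_weights
#' @export
weights_cer <- function(g, invert = FALSE) {
  check_graph(g); check_nonempty_edges(g)
  deg <- igraph::degree(g)
  h <- 1 / (1 + abs(deg - mean(deg)))
  if (invert) h <- 1 - h
  nw <- stats::setNames(as.numeric(h), node_names(g))
  new_removal_distribution(g, endpoint_sum_weights(g, h),
                           if (invert) "cer_invert" else "cer", nw)
}

#' @rdname edge_weights
#' @export
weights_rnber <- function(g, values = NULL) {
  check_graph(g); check_nonempty_edges(g)
  nm <- node_names(g)
  if (is.null(values)) {
    r <- stats::runif(igraph::vcount(g))
  } else {
    if (is.null(names(values))) {
      if (length(values) != length(nm)) abort("`values` must have one entry per node.")
      r <- as.numeric(values)
    } else {
      missing <- setdiff(nm, names(values))
      if (length(missing)) abort(sprintf("`values` missing nodes: %s", paste(missing, collapse = ", ")))
      r <- as.numeric(values[nm])
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  raw <- r[el[, 1]] * r[el[, 2]]
  new_removal_distribution(g, raw, "rnber", stats::setNames(r, nm))
}

#' @rdname edge_weights
#' @export
weights_rwer <- function(g, damping = 0.85) {
  check_graph(g); check_nonempty_edges(g)
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    abort("`damping` must be in (0, 1).")
  }
  pr <- igraph::page_rank(g, damping = damping)$vector
  new_removal_distribution(g, endpoint_sum_weights(g, pr), "rwer",
                           stats::setNames(as.numeric(pr), node_names(g)))
}

#' Draw a weighted removal set of edges
#'
#' Selects exactly `round(fraction * |E|)` distinct edges (round half to
#' even) without replacement, with selection probabilities proportional to a
#' scheme's removal weights. Under the default `"static"` policy the weights
#' come from the intact graph once; under `"every-k"` they are recomputed on
#' the residual graph after every `refresh_k` removals.
#'
#' The sequential conditional distribution (draw one edge proportionally to
#' weight, renormalise over the remainder, repeat) is realised with
#' exponential race keys: edge `e` receives key `Exp(1)/w(e)` and the
#' smallest keys are removed first, which is distributionally identical.
#'
#' @param g Undirected simple graph.
#' @param dist An `edge_removal_distribution`, or a method name passed to
#'   [edge_weights()].
#' @param fraction Fraction of edges to remove, in `[0, 1]`.
#' @param policy `"static"` or `"every-k"`.
#' @param refresh_k Recomputation interval for `"every-k"`.
#' @param ... Passed to [edge_weights()] when `dist` is a method name.
#' @return A tibble of removed edges (`from`, `to`), ordered as drawn.
#' @export
sample_removal_set <- function(g, dist, fraction, policy = c("static", "every-k"),
                               refresh_k = 1L, ...) {
  check_graph(g)
  policy <- match.arg(policy)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    abort("`fraction` must be in [0, 1].")
  }
  n_remove <- round(fraction * igraph::ecount(g))
  if (n_remove == 0L) return(tibble(from = character(), to = character()))

  if (is.character(dist)) {
    method <- dist
    dist <- edge_weights(g, method, ...)
  } else {
    method <- attr(dist, "scheme")
  }
  if (!inherits(dist, "edge_removal_distribution")) {
    abort("`dist` must be an edge_removal_distribution or a method name.")
  }
  if (nrow(dist) != igraph::ecount(g)) {
    abort("`dist` does not match the graph's current edge set.")
  }

  if (policy == "static") {
    idx <- exp_race_draw(dist$weight, n_remove)
    return(tibble(from = dist$from[idx], to = dist$to[idx]))
  }

  if (!is.numeric(refresh_k) || refresh_k < 1) abort("`refresh_k` must be >= 1.")
  out_from <- character(n_remove); out_to <- character(n_remove)
  residual <- g
  cur <- dist
  taken <- 0L
  while (taken < n_remove) {
    batch <- min(as.integer(refresh_k), n_remove - taken)
    idx <- exp_race_draw(cur$weight, batch)
    out_from[taken + seq_len(batch)] <- cur$from[idx]
    out_to[taken + seq_len(batch)] <- cur$to[idx]
    taken <- taken + batch
    residual <- igraph::delete_edges(
      residual, paste(cur$from[idx], cur$to[idx], sep = "|")
    )
    if (taken < n_remove) cur <- edge_weights(residual, method, ...)
  }
  tibble(from = out_from, to = out_to)
}

# Efraimidis-Spirtes weighted reservoir: k smallest Exp(1)/w keys.
# Zero-weight items get +Inf keys and are only taken once positive-weight
# support is exhausted.
exp_race_draw <- function(w, k) {
  keys <- stats::rexp(length(w)) / w
  order(keys)[seq_len(k)]
}

#' Remove an edge set from a graph
#'
#' Returns a new graph with the same node set (isolated nodes are retained)
#' and the given edges deleted. Every listed edge must be present.
#'
#' @param g Undirected simple graph.
#' @param removed A tibble/data frame with `from` and `to` columns, as
#'   returned by [sample_removal_set()].
#' @return The reduced graph.
#' @export
apply_removal <- function(g, removed) {
  check_graph(g)
  if (nrow(removed) == 0L) return(g)
  known <- node_names(g)
  if (!all(c(removed$from, removed$to) %in% known)) {
    abort("`removed` contains edges not present in the graph.")
  }
  eids <- igraph::get_edge_ids(g, rbind(removed$from, removed$to))
  if (any(eids == 0)) {
    abort("`removed` contains edges not present in the graph.")
  }
  if (anyDuplicated(eids)) abort("`removed` lists the same edge twice.")
  igraph::delete_edges(g, eids)
}

#' @export
print.edge_removal_distribution <- function(x, ...) {
  cat(sprintf("<edge_removal_distribution> scheme: %s, %d edges\n",
              attr(x, "scheme"), nrow(x)))
  NextMethod()
}

#' Write a removal set as an annotated edge-list TSV
#'
#' @param removed Removal set tibble.
#' @param path Output path.
#' @param scheme,fraction,seed,policy Provenance recorded in the header.
#' @export
write_removal_set <- function(removed, path, scheme = NA, fraction = NA,
                              seed = NA, policy = "static") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s fraction=%s seed=%s policy=%s",
                     scheme, fraction, seed, policy), con)
  writeLines(paste(removed$from, removed$to, sep = "\t"), con)
  invisible(path)
}
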