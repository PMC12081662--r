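#' Node centrality scores
#'
#' Computes one of six centrality measures on a possibly-disconnected
#' undirected graph and returns a score for every node, including isolated
#' ones. Conventions:
#'
#' * **degree** — raw incident-edge count.
#' * **betweenness** — exact (Brandes), normalised by `(n-1)(n-2)/2`,
#'   endpoints excluded.
#' * **closeness** — Wasserman–Faust generalisation for disconnected
#'   graphs: for node `v` reaching `R` other nodes at total distance `S`,
#'   closeness is `(R / (n-1)) * (R / S)`; isolated nodes score 0.
#' * **eigenvector** — principal eigenvector of the adjacency matrix,
#'   L2-normalised, nonnegative; nodes outside the dominant component get
#'   (numerically) zero.
#' * **pagerank** — damping `damping`, uniform teleport over all nodes, so
#'   isolated nodes keep teleport mass; scores sum to 1.
#' * **subgraph** — diagonal of the matrix exponential of the adjacency
#'   matrix, via dense symmetric eigendecomposition
#'   `sum_i u_iv^2 exp(lambda_i)`; O(n^3), intended for n up to a few
#'   thousand. When `lambda_max` would overflow `exp()` the whole vector is
#'   scaled by `exp(-lambda_max)` (rank-preserving; flagged in the
#'   `scaled` attribute).
#'
#' @param g Undirected simple graph.
#' @param measure One of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`, `"pagerank"`, `"subgraph"`.
#' @param damping PageRank damping factor.
#' @return A tibble `node`, `score` (one row per node, graph order) of
#'   class `centrality_vector`, with the measure in attribute `measure`.
#' @examples
#' compute_centrality(toy_fixture("star4"), "degree")
#' @export
compute_centrality <- function(g, measure, damping = 0.85) {
  check_graph(g)
  measure <- tolower(measure)
  if (!measure %in% centrality_measures()) {
    abort(sprintf("unknown centrality measure '%s'.", measure))
  }
  scores <- centrality_scores(g, measure, damping)
  structure(
    tibble(node = node_names(g), score = as.numeric(scores)),
    measure = measure,
    scaled = isTRUE(attr(scores, "scaled")),
    class = c("centrality_vector", class(tibble()))
  )
}

#' @export
centrality_measures <- function() {
  c("degree", "betweenness", "closeness", "eigenvector", "pagerank", "subgraph")
}

centrality_scores <- function(g, measure, damping = 0.85) {
  n <- igraph::vcount(g)
  if (measure == "degree") return(as.numeric(igraph::degree(g)))
  if (measure == "pagerank") {
    return(as.numeric(igraph::page_rank(g, damping = damping)$vector))
  }
  if (measure == "betweenness") {
    if (n < 3) return(numeric(n))
    return(as.numeric(igraph::betweenness(g, normalized = TRUE)))
  }
  if (measure == "closeness") return(closeness_wf(g))
  if (igraph::ecount(g) == 0L) {
    # edgeless graph: adjacency is zero, exp(0) = I
    return(if (measure == "subgraph") rep(1, n) else numeric(n))
  }
  if (measure == "eigenvector") {
    ev <- igraph::eigen_centrality(g)$vector
    ev <- abs(as.numeric(ev))
    nrm <- sqrt(sum(ev^2))
    return(if (nrm > 0) ev / nrm else ev)
  }
  subgraph_scores(g)
}

closeness_wf <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1L) return(numeric(n))
  d <- igraph::distances(g)
  diag(d) <- Inf
  reach <- is.finite(d)
  R <- rowSums(reach)
  S <- rowSums(ifelse(reach, d, 0))
  out <- ifelse(R > 0, (R / (n - 1)) * (R / S), 0)
  as.numeric(out)
}

subgraph_scores <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  eig <- eigen(A, symmetric = TRUE)
  lmax <- eig$values[1]
  shift <- if (lmax > 700) lmax else 0
  sc <- as.numeric((eig$vectors^2) %*% exp(eig$values - shift))
  attr(sc, "scaled") <- shift > 0
  sc
}

#' Tie-aware descending ranks
#'
#' Converts centrality scores to ranks with 1 = most central; tied scores
#' receive the average of the positions they span, so ranks always sum to
#' `n(n+1)/2`.
#'
#' @param cv A `centrality_vector` tibble (or any tibble with `node` and
#'   `score` columns).
#' @return The input with a `rank` column appended.
#' @export
rank_scores <- function(cv) {
  cv$rank <- rank_desc(cv$score)
  cv
}

rank_desc <- function(x) rank(-x, ties.method = "average")

#' Centrality score/rank table across measures
#'
#' @param g Undirected simple graph.
#' @param measures Character vector of measures (default all six).
#' @param damping PageRank damping factor.
#' @return A long tibble: `node`, `measure`, `score`, `rank`.
#' @export
centrality_table <- function(g, measures = centrality_measures(), damping = 0.85) {
  purrr::map_dfr(measures, function(m) {
    cv <- rank_scores(compute_centrality(g, m, damping = damping))
    tibble(node = cv$node, measure = m, score = cv$score, rank = cv$rank)
  })
}
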