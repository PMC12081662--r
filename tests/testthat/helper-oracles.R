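# Independent brute-force oracles, deliberately naive: these share no code
# with the package implementation.

# Betweenness by exhaustive simple-path enumeration (feasible for n <= 7).
# Returns the normalized, endpoint-excluded convention.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return()
      }
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    paths
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      for (v in interior) btw[v] <- btw[v] + 1 / sigma
    }
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  stats::setNames(btw, igraph::V(g)$name %||% as.character(seq_len(n)))
}

# Subgraph centrality by truncated power series sum_{k<=kmax} (A^k)_vv / k!.
oracle_subgraph <- function(g, kmax = 30) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  n <- nrow(A)
  acc <- diag(n)       # k = 0 term
  Ak <- diag(n)
  fact <- 1
  for (k in seq_len(kmax)) {
    Ak <- Ak %*% A
    fact <- fact * k
    acc <- acc + Ak / fact
  }
  diag(acc)
}

# PageRank by plain power iteration with uniform teleport; dangling mass is
# redistributed uniformly.
oracle_pagerank <- function(g, d = 0.85, tol = 1e-13, max_iter = 10000) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  deg <- rowSums(A)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    spread <- ifelse(deg > 0, x / deg, 0)
    dangling <- sum(x[deg == 0])
    x_new <- (1 - d) / n + d * (as.numeric(spread %*% A) + dangling / n)
    if (max(abs(x_new - x)) < tol) return(x_new / sum(x_new))
    x <- x_new
  }
  x / sum(x)
}

# Exact inclusion probabilities for sequential weighted draws without
# replacement, by recursion over all ordered sequences.
oracle_inclusion_probs <- function(w, k) {
  m <- length(w)
  incl <- numeric(m)
  recur <- function(remaining, prob, depth) {
    if (depth == k) return()
    total <- sum(w[remaining])
    for (i in remaining) {
      p_i <- prob * w[i] / total
      incl[i] <<- incl[i] + p_i
      recur(setdiff(remaining, i), p_i, depth + 1L)
    }
  }
  recur(seq_len(m), 1, 0L)
  incl
}

# Spearman via independent counting ranks + explicit Pearson formula.
oracle_spearman <- function(x, y) {
  count_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v > v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- count_rank(x); ry <- count_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_small_graph <- function(n, p = 0.5) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}
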