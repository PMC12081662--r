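#' Generate an Erdős–Rényi random graph
#'
#' Samples a G(n, p) graph: every unordered node pair is an edge
#' independently with probability `p`. The expected edge count is
#' `p * n * (n - 1) / 2`. Nodes are labelled `"v1" ... "vn"`.
#'
#' @param n Number of nodes (>= 2).
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return A simple undirected `igraph` object with character node names.
#' @examples
#' g <- generate_erdos_renyi(100, 0.1, seed = 1)
#' igraph::ecount(g)
#' @export
generate_erdos_renyi <- function(n, p, seed = 1L) {
  if (!is.numeric(n) || n < 2 || n != round(n)) abort("`n` must be an integer >= 2.")
  if (!is.numeric(p) || p < 0 || p > 1) abort("`p` must be a probability in [0, 1].")
  g <- withr::with_seed(as.integer(seed), igraph::sample_gnp(as.integer(n), p, directed = FALSE))
  label_graph(g)
}

#' Generate a Barabási–Albert scale-free graph
#'
#' Preferential-attachment growth starting from `m` isolated seed nodes:
#' each of the remaining `n - m` nodes joins with `m` edges to existing
#' nodes, chosen proportionally to current degree (uniformly while all
#' degrees are zero). The edge count is exactly `m * (n - m)`.
#'
#' The first arriving node connects to all `m` seed nodes; afterwards
#' targets are drawn by the repeated-endpoint-list construction, which
#' realises linear preferential attachment without replacement within a
#' step (no multi-edges, no self-loops).
#'
#' @param n Number of nodes.
#' @param m Attachment count, integer with `1 <= m < n`.
#' @param seed Integer seed.
#' @return A simple undirected `igraph` object.
#' @examples
#' g <- generate_barabasi_albert(200, 3, seed = 1)
#' igraph::ecount(g) == 3 * (200 - 3)
#' @export
generate_barabasi_albert <- function(n, m, seed = 1L) {
  if (!is.numeric(n) || n < 2 || n != round(n)) abort("`n` must be an integer >= 2.")
  if (!is.numeric(m) || m < 1 || m != round(m) || m >= n) {
    abort("`m` must be an integer with 1 <= m < n.")
  }
  n <- as.integer(n); m <- as.integer(m)
  withr::with_seed(as.integer(seed), {
    # repeated-endpoint list: each edge contributes both endpoints, so
    # sampling uniformly from it is degree-proportional sampling.
    rep_list <- integer(2L * m * (n - m))
    fill <- 0L
    edges <- integer(2L * m * (n - m))
    eptr <- 0L
    for (v in (m + 1L):n) {
      if (fill == 0L) {
        targets <- seq_len(m)          # all degrees zero: attach to every seed node
      } else {
        targets <- integer(0)
        # rejection sampling over the endpoint list until m distinct targets
        while (length(targets) < m) {
          cand <- rep_list[sample.int(fill, m - length(targets), replace = TRUE)]
          targets <- unique(c(targets, cand))
        }
        targets <- targets[seq_len(m)]
      }
      for (t in targets) {
        edges[eptr + 1L] <- v; edges[eptr + 2L] <- t
        eptr <- eptr + 2L
        rep_list[fill + 1L] <- v; rep_list[fill + 2L] <- t
        fill <- fill + 2L
      }
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, edges)
    label_graph(g)
  })
}

#' Generate a Watts–Strogatz small-world graph
#'
#' A ring lattice in which every node is joined to its `k` nearest ring
#' neighbours, with each edge rewired to a uniformly chosen endpoint with
#' probability `beta`. Rewiring preserves the edge count, so `|E| = n * k / 2`
#' for every `beta`.
#'
#' @param n Number of nodes.
#' @param k Even ring degree, `0 < k < n`.
#' @param beta Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A simple undirected `igraph` object.
#' @export
generate_watts_strogatz <- function(n, k, beta, seed = 1L) {
  if (!is.numeric(n) || n < 2 || n != round(n)) abort("`n` must be an integer >= 2.")
  if (!is.numeric(k) || k != round(k) || k %% 2 != 0 || k <= 0 || k >= n) {
    abort("`k` must be a positive even integer < n.")
  }
  if (!is.numeric(beta) || beta < 0 || beta > 1) abort("`beta` must be in [0, 1].")
  g <- withr::with_seed(
    as.integer(seed),
    igraph::sample_smallworld(1, as.integer(n), as.integer(k) %/% 2L, beta,
                              loops = FALSE, multiple = FALSE)
  )
  label_graph(g)
}

label_graph <- function(g) {
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}

#' Read an undirected graph from a two-column edge list
#'
#' Whitespace- or tab-delimited, two labels per line; lines starting with
#' `#` are comments. Direction is discarded, duplicate edges are collapsed
#' and self-loops dropped (a message reports how many).
#'
#' @param path Path to the edge-list file.
#' @return A simple undirected `igraph` object with character node names.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("edge-list file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(rows) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed edge-list line %d: expected two labels, got %d.",
                  which(keep)[bad[1]], lengths(rows)[bad[1]]))
  }
  from <- vapply(rows, `[[`, character(1), 1L)
  to <- vapply(rows, `[[`, character(1), 2L)
  loops <- from == to
  if (any(loops)) {
    message(sprintf("read_edge_list: dropped %d self-loop(s).", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  keys <- edge_keys(from, to)
  dup <- duplicated(keys)
  from <- from[!dup]; to <- to[!dup]
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  g
}

#' Write a graph as a two-column edge-list TSV
#'
#' @param g Undirected graph.
#' @param path Output path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, header = NULL) {
  check_graph(g)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  et <- edge_tibble(g)
  writeLines(paste(et$from, et$to, sep = "\t"), con)
  invisible(path)
}

#' Read / write GraphML
#'
#' Thin wrappers over igraph's GraphML support; directed input is
#' symmetrised and simplified on read.
#'
#' @param path File path.
#' @return An undirected simple `igraph` object (`read_graphml`), or `path`
#'   invisibly (`write_graphml`).
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) abort(sprintf("GraphML file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  as_undirected_simple(g)
}

#' @rdname read_graphml
#' @param g Graph to write.
#' @export
write_graphml <- function(g, path) {
  check_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Coerce a graph to simple undirected form
#'
#' Drops direction, self-loops and duplicate edges. Directed networks are
#' treated as undirected throughout this package.
#'
#' @param g An igraph object.
#' @return A simple undirected igraph object.
#' @export
as_undirected_simple <- function(g) {
  g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Small named fixture graphs
#'
#' Deterministic toy graphs used in examples and tests: `"k2"` (one edge),
#' `"path4"` (4-node path), `"star4"` (centre plus four leaves), `"kite"`
#' (edges ab, bc, bd, cd), `"cycle6"` (6-cycle), `"bowtie8"` (two squares
#' joined by a bridge edge; 8 nodes, 9 edges).
#'
#' @param name One of `"path4"`, `"star4"`, `"kite"`, `"k2"`, `"cycle6"`,
#'   `"bowtie8"`.
#' @return A simple undirected `igraph` object.
#' @examples
#' igraph::degree(toy_fixture("kite"))
#' @export
toy_fixture <- function(name) {
  edges <- switch(name,
    k2      = c("a","b"),
    path4   = c("a","b", "b","c", "c","d"),
    star4   = c("c","l1", "c","l2", "c","l3", "c","l4"),
    kite    = c("a","b", "b","c", "b","d", "c","d"),
    cycle6  = c("a","b", "b","c", "c","d", "d","e", "e","f", "f","a"),
    bowtie8 = c("a","b", "b","c", "c","d", "d","a", "d","e",
                "e","f", "f","g", "g","h", "h","e"),
    abort(sprintf("unknown fixture name '%s'.", name))
  )
  igraph::make_graph(edges, directed = FALSE)
}

#' Summarise a graph as a one-row tibble
#'
#' @param g Undirected graph.
#' @param id Optional identifier recorded in the `network` column.
#' @return A tibble with node/edge counts and degree summaries.
#' @export
graph_summary <- function(g, id = NA_character_) {
  check_graph(g)
  deg <- igraph::degree(g)
  tibble(
    network = id,
    nodes = igraph::vcount(g),
    edges = igraph::ecount(g),
    mean_degree = mean(deg),
    max_degree = if (length(deg)) max(deg) else 0L
  )
}
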