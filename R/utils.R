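#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# MINSTD-style rolling hash used to derive per-cell RNG seeds from a master
# seed plus arbitrary string/integer components. Stays below 2^31 - 1 so the
# result is always a valid 32-bit seed, and intermediate products stay well
# below 2^53 (double-precision exactness).
hash_seed <- function(master_seed, ...) {
  m <- 2147483647
  acc <- as.numeric(master_seed) %% m
  for (comp in list(...)) {
    if (is.character(comp)) {
      comp <- sum(utf8ToInt(comp) * seq_along(utf8ToInt(comp))) %% m
    }
    acc <- (acc * 48271 + as.numeric(comp) + 1) %% m
  }
  as.integer(acc)
}

check_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) {
    abort(sprintf("`%s` must be an igraph object (see generate_* or read_edge_list()).", arg))
  }
  if (igraph::is_directed(g)) {
    abort(sprintf("`%s` must be undirected; use as_undirected_simple() on directed input.", arg))
  }
  invisible(g)
}

check_nonempty_edges <- function(g) {
  if (igraph::ecount(g) < 1L) abort("graph has an empty edge set; removal weights are undefined.")
  invisible(g)
}

node_names <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

# Canonical "u|v" edge keys with endpoints in sorted order, so an undirected
# edge compares equal regardless of orientation.
edge_keys <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "|")
}

edge_tibble <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) {
    return(tibble(from = character(), to = character()))
  }
  tibble(from = as.character(el[, 1]), to = as.character(el[, 2]))
}
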