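#' Per-node rank trajectories across removal levels
#'
#' For each removal level, one removal set is drawn from the intact graph
#' (fresh-draw semantics, seed derived per level), the measure is computed
#' on the reduced graph, and every original node's tie-averaged rank is
#' recorded. Level 0 (the intact ranking) is not included by default;
#' pass it explicitly in `levels` to include it.
#'
#' @param g Undirected simple graph.
#' @param method A removal method.
#' @param measure A centrality measure.
#' @param levels Removal levels in `[0, 1)`..`[0,1]`, strictly increasing;
#'   default 0.1..0.9.
#' @param master_seed Integer master seed.
#' @param network_id Identifier used in seed derivation.
#' @param damping,cer_invert See [edge_weights()].
#' @return A long tibble `node`, `level`, `rank` of class
#'   `rank_trajectories` (method/measure/seed in attributes).
#' @export
rank_trajectories <- function(g, method, measure,
                              levels = seq(0.1, 0.9, by = 0.1),
                              master_seed = 1L, network_id = "network",
                              damping = 0.85, cer_invert = FALSE) {
  check_graph(g)
  if (length(levels) == 0L) abort("`levels` must be nonempty.")
  if (is.unsorted(levels, strictly = TRUE)) abort("`levels` must be strictly increasing.")
  nodes <- node_names(g)
  out <- purrr::map_dfr(seq_along(levels), function(li) {
    f <- levels[li]
    seed <- hash_seed(master_seed, network_id, method, li, 1L)
    reduced <- withr::with_seed(seed, {
      rem <- sample_removal_set(g, method, f, damping = damping,
                                cer_invert = cer_invert)
      apply_removal(g, rem)
    })
    r <- rank_desc(centrality_scores(reduced, measure, damping))
    tibble(node = nodes, level = f, rank = r)
  })
  structure(out, method = method, measure = measure,
            master_seed = master_seed,
            class = c("rank_trajectories", class(tibble())))
}

#' Rank-variability stability threshold
#'
#' The configured percentile (default 25th) of the per-node rank standard
#' deviations, computed with linear interpolation between order statistics.
#'
#' @param stds Nonempty numeric vector of rank standard deviations.
#' @param percentile Percentile as a proportion (default 0.25).
#' @return The threshold value.
#' @examples
#' stability_threshold(c(0, 1, 2, 3))  # 0.75
#' @export
stability_threshold <- function(stds, percentile = 0.25) {
  if (length(stds) == 0L) abort("`stds` must be nonempty.")
  unname(stats::quantile(stds, probs = percentile, type = 7))
}

#' Per-node stability profile
#'
#' Summarises rank trajectories into each node's mean rank and rank
#' standard deviation across removal levels, thresholds the standard
#' deviations at the given percentile, and flags nodes strictly below the
#' threshold as stable.
#'
#' @param traj A `rank_trajectories` tibble, or a graph (in which case the
#'   trajectories are computed first and `...` is passed to
#'   [rank_trajectories()]).
#' @param percentile Threshold percentile (proportion, default 0.25).
#' @param ... Passed to [rank_trajectories()] when `traj` is a graph.
#' @return A `stability_profile` tibble: `node`, `mean_rank`, `rank_std`,
#'   `stable`; threshold and percentile in attributes. [tidy()] returns the
#'   table, [glance()] the threshold and stable-node count.
#' @export
stability_profile <- function(traj, percentile = 0.25, ...) {
  if (igraph::is_igraph(traj)) traj <- rank_trajectories(traj, ...)
  prof <- dplyr::summarise(
    dplyr::group_by(traj, .data$node),
    mean_rank = mean(.data$rank),
    rank_std = stats::sd(.data$rank),
    .groups = "drop"
  )
  if (dplyr::n_distinct(traj$level) < 2L) prof$rank_std <- 0
  thr <- stability_threshold(prof$rank_std, percentile)
  prof$stable <- prof$rank_std < thr
  structure(prof,
            threshold = thr, percentile = percentile,
            method = attr(traj, "method"), measure = attr(traj, "measure"),
            class = c("stability_profile", class(tibble())))
}

#' Nodes classified as stable
#'
#' @param profile A `stability_profile`.
#' @return Character vector of node labels with rank standard deviation
#'   strictly below the threshold.
#' @export
stable_nodes <- function(profile) {
  profile$node[profile$stable]
}

#' Percentage of stable nodes per (method, measure) cell
#'
#' Runs the stability pipeline for every combination of removal method and
#' centrality measure and reports the percentage of denominator nodes
#' classified as stable. The same per-level removal draw is shared by all
#' measures within a method.
#'
#' @param g Undirected simple graph.
#' @param methods,measures Methods and measures to cross.
#' @param levels Removal levels (default 0.1..0.9).
#' @param master_seed Integer master seed.
#' @param denominator Optional character vector of node labels to use as
#'   the reference set (default: all nodes).
#' @param percentile Threshold percentile.
#' @param damping,cer_invert See [edge_weights()].
#' @return A tibble `method`, `measure`, `pct_stable`, `n_stable`,
#'   `n_denominator`; the per-cell `stability_profile`s are in the
#'   `profiles` attribute (named `method.measure`).
#' @export
stability_table <- function(g, methods = removal_methods(),
                            measures = centrality_measures(),
                            levels = seq(0.1, 0.9, by = 0.1),
                            master_seed = 1L, denominator = NULL,
                            percentile = 0.25, damping = 0.85,
                            cer_invert = FALSE) {
  check_graph(g)
  nodes <- node_names(g)
  if (is.null(denominator)) denominator <- nodes
  if (length(denominator) == 0L) abort("`denominator` must be nonempty.")
  if (!all(denominator %in% nodes)) abort("`denominator` contains unknown node labels.")

  profiles <- list()
  rows <- purrr::map_dfr(methods, function(method) {
    # draw each level's reduced graph once per method, share across measures
    reduced_by_level <- lapply(seq_along(levels), function(li) {
      seed <- hash_seed(master_seed, "stability", method, li, 1L)
      withr::with_seed(seed, {
        rem <- sample_removal_set(g, method, levels[li], damping = damping,
                                  cer_invert = cer_invert)
        apply_removal(g, rem)
      })
    })
    purrr::map_dfr(measures, function(measure) {
      traj <- purrr::map_dfr(seq_along(levels), function(li) {
        r <- rank_desc(centrality_scores(reduced_by_level[[li]], measure, damping))
        tibble(node = nodes, level = levels[li], rank = r)
      })
      traj <- structure(traj, method = method, measure = measure,
                        class = c("rank_trajectories", class(tibble())))
      prof <- stability_profile(traj, percentile = percentile)
      profiles[[paste(method, measure, sep = ".")]] <<- prof
      stable <- stable_nodes(prof)
      tibble(method = method, measure = measure,
             pct_stable = 100 * length(intersect(stable, denominator)) /
               length(denominator),
             n_stable = length(intersect(stable, denominator)),
             n_denominator = length(denominator))
    })
  })
  structure(rows, profiles = profiles, class = c("stability_table", class(tibble())))
}

#' Read a node-subset file (one label per line)
#'
#' @param path File path; `#` comment lines and blanks ignored.
#' @return Character vector of node labels.
#' @export
read_node_subset <- function(path) {
  if (!file.exists(path)) abort(sprintf("node-subset file not found: %s", path))
  lines <- trimws(readr::read_lines(path))
  lines[!grepl("^(#|$)", lines)]
}

#' @export
tidy.stability_profile <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.stability_profile <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    measure = attr(x, "measure") %||% NA_character_,
    threshold = attr(x, "threshold"),
    percentile = attr(x, "percentile"),
    n_nodes = nrow(x),
    n_stable = sum(x$stable),
    pct_stable = 100 * mean(x$stable)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
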