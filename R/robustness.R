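#' Spearman rank correlation (rank-then-Pearson)
#'
#' Ranks both vectors with average ties (descending, 1 = highest) and
#' returns the Pearson correlation of the ranks. When either rank vector is
#' constant the correlation is undefined and `NA` is returned rather than a
#' fabricated value.
#'
#' @param x,y Numeric score vectors of equal length (>= 2), in a common
#'   node order.
#' @return A correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(c(1, 2, 2, 4), c(1, 2, 3, 4))  # 0.9486833
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("need at least two observations.")
  rx <- rank_desc(x)
  ry <- rank_desc(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Run the edge-removal robustness protocol
#'
#' The core experiment: for each removal method, fraction and replicate,
#' draw a removal set from the intact graph (fresh-draw semantics), delete
#' it, recompute each centrality measure on the reduced graph over the
#' identical node set, and Spearman-correlate against the intact ranking.
#'
#' Seeds are derived deterministically from
#' `(master_seed, network id, method, fraction index, replicate index)` so
#' any single cell can be reproduced in isolation; the same removal draw is
#' shared by all measures. Replicates where a measure fails or the
#' correlation is undefined (constant ranks) record `NA`.
#'
#' @param g Undirected simple graph.
#' @param methods Removal methods (subset of [removal_methods()]).
#' @param measures Centrality measures (subset of [centrality_measures()]).
#' @param fractions Removal fractions in `(0, 1]`, strictly increasing.
#' @param replicates Independent replicates per (method, fraction).
#' @param master_seed Integer master seed.
#' @param network_id Identifier recorded in the output.
#' @param cumulative If `TRUE`, fractions are nested within a replicate:
#'   each level removes additional edges from the previous level's residual
#'   graph instead of drawing afresh from the intact graph.
#' @param policy,refresh_k Weight-refresh policy, see
#'   [sample_removal_set()].
#' @param damping PageRank damping (weights and centrality).
#' @param cer_invert See [edge_weights()].
#' @return A long tibble: `network`, `method`, `measure`, `fraction`,
#'   `replicate`, `rho`.
#' @export
robustness_run <- function(g, methods = removal_methods(),
                           measures = centrality_measures(),
                           fractions = seq(0.1, 0.9, by = 0.1),
                           replicates = 10L, master_seed = 1L,
                           network_id = "network", cumulative = FALSE,
                           policy = "static", refresh_k = 1L,
                           damping = 0.85, cer_invert = FALSE) {
  check_graph(g)
  if (any(fractions < 0 | fractions > 1)) abort("`fractions` must lie in [0, 1].")
  if (is.unsorted(fractions, strictly = TRUE)) {
    abort("`fractions` must be strictly increasing.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")

  intact_ranks <- lapply(stats::setNames(measures, measures), function(m) {
    rank_desc(centrality_scores(g, m, damping))
  })

  grid <- tidyr::expand_grid(method = methods, replicate = seq_len(replicates))
  rows <- purrr::pmap_dfr(grid, function(method, replicate) {
    residual <- g
    prev_fraction <- 0
    purrr::map_dfr(seq_along(fractions), function(fi) {
      f <- fractions[fi]
      seed <- hash_seed(master_seed, network_id, method, fi, replicate)
      reduced <- withr::with_seed(seed, {
        if (cumulative) {
          extra <- round(f * igraph::ecount(g)) - round(prev_fraction * igraph::ecount(g))
          frac_res <- if (igraph::ecount(residual) > 0)
            extra / igraph::ecount(residual) else 0
          rem <- sample_removal_set(residual, method, min(max(frac_res, 0), 1),
                                    policy = policy, refresh_k = refresh_k,
                                    damping = damping, cer_invert = cer_invert)
          apply_removal(residual, rem)
        } else {
          rem <- sample_removal_set(g, method, f, policy = policy,
                                    refresh_k = refresh_k, damping = damping,
                                    cer_invert = cer_invert)
          apply_removal(g, rem)
        }
      })
      if (cumulative) {
        residual <<- reduced
        prev_fraction <<- f
      }
      rho <- vapply(measures, function(m) {
        sc <- tryCatch(centrality_scores(reduced, m, damping),
                       error = function(e) NULL)
        if (is.null(sc)) return(NA_real_)
        spearman_rho(intact_ranks[[m]], rank_desc(sc))
      }, numeric(1))
      tibble(network = network_id, method = method, measure = measures,
             fraction = f, replicate = replicate, rho = unname(rho))
    })
  })
  rows
}

#' Robustness curve for one (method, measure) pair
#'
#' Convenience wrapper around [robustness_run()] returning a
#' `robustness_curve` tibble of per-replicate Spearman rho values, with
#' [tidy()] (per-fraction mean/sd/n), [glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams robustness_run
#' @param method A single removal method.
#' @param measure A single centrality measure.
#' @param ... Passed to [robustness_run()].
#' @return A `robustness_curve` tibble: `fraction`, `replicate`, `rho`.
#' @export
robustness_curve <- function(g, method, measure,
                             fractions = seq(0.1, 0.9, by = 0.1),
                             replicates = 10L, master_seed = 1L,
                             network_id = "network", ...) {
  stopifnot(length(method) == 1L, length(measure) == 1L)
  res <- robustness_run(g, methods = method, measures = measure,
                        fractions = fractions, replicates = replicates,
                        master_seed = master_seed, network_id = network_id, ...)
  structure(
    res[, c("fraction", "replicate", "rho")],
    network = network_id, method = method, measure = measure,
    master_seed = master_seed,
    class = c("robustness_curve", class(tibble()))
  )
}

#' Aggregate replicate rho values per cell
#'
#' @param runs Long tibble from [robustness_run()].
#' @return One row per (network, method, measure, fraction) with
#'   `mean_rho`, `sd_rho` and `n_rho` (replicates with a defined
#'   correlation).
#' @export
summarise_robustness <- function(runs) {
  dplyr::summarise(
    dplyr::group_by(runs, dplyr::across(dplyr::any_of(
      c("network", "method", "measure", "fraction")))),
    mean_rho = mean(.data$rho, na.rm = TRUE),
    sd_rho = stats::sd(.data$rho, na.rm = TRUE),
    n_rho = sum(!is.na(.data$rho)),
    .groups = "drop"
  )
}

#' Robustness matrix at a single removal fraction
#'
#' The data behind a (network x method) by measure heatmap of mean rank
#' correlations at one stated removal fraction.
#'
#' @param graphs Named list of undirected graphs.
#' @param methods,measures,replicates,master_seed See [robustness_run()].
#' @param fraction A single removal fraction in `(0, 1)`.
#' @param ... Passed to [robustness_run()].
#' @return A tibble: `network`, `method`, `measure`, `mean_rho`, `sd_rho`,
#'   `n_rho`.
#' @export
robustness_matrix <- function(graphs, methods = removal_methods(),
                              measures = centrality_measures(),
                              fraction = 0.3, replicates = 10L,
                              master_seed = 1L, ...) {
  if (length(fraction) != 1L || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single value in (0, 1).")
  }
  if (is.null(names(graphs))) names(graphs) <- paste0("network", seq_along(graphs))
  runs <- purrr::imap_dfr(graphs, function(g, id) {
    robustness_run(g, methods = methods, measures = measures,
                   fractions = fraction, replicates = replicates,
                   master_seed = master_seed, network_id = id, ...)
  })
  summarise_robustness(runs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.robustness_curve <- function(x, ...) {
  out <- summarise_robustness(
    tibble(network = attr(x, "network"), method = attr(x, "method"),
           measure = attr(x, "measure"), fraction = x$fraction,
           replicate = x$replicate, rho = x$rho))
  out
}

#' @export
glance.robustness_curve <- function(x, ...) {
  td <- tidy(x)
  tibble(
    network = attr(x, "network"), method = attr(x, "method"),
    measure = attr(x, "measure"),
    n_fractions = nrow(td),
    replicates = max(x$replicate),
    mean_rho = mean(x$rho, na.rm = TRUE),
    min_mean_rho = min(td$mean_rho),
    auc_rho = mean(td$mean_rho)
  )
}
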