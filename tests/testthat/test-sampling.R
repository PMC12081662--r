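kite <- toy_fixture("kite")
kite_keys <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to), sep = "|")

test_that("scheme weights on the kite match hand-derived values", {
  rer <- edge_weights(kite, "rer")
  expect_equal(rer$weight, rep(1 / 4, 4))

  hcer <- edge_weights(kite, "hcer")
  expect_equal(
    stats::setNames(hcer$weight, kite_keys(hcer))[c("a|b", "b|c", "b|d", "c|d")],
    c("a|b" = 2 / 9, "b|c" = 5 / 18, "b|d" = 5 / 18, "c|d" = 2 / 9)
  )

  lcer <- edge_weights(kite, "lcer")
  expect_equal(
    stats::setNames(lcer$weight, kite_keys(lcer))[c("a|b", "b|c", "b|d", "c|d")],
    c("a|b" = 2 / 7, "b|c" = 3 / 14, "b|d" = 3 / 14, "c|d" = 2 / 7)
  )

  cer <- edge_weights(kite, "cer")
  expect_equal(
    stats::setNames(cer$weight, kite_keys(cer))[c("a|b", "b|c", "b|d", "c|d")],
    c("a|b" = 1 / 6, "b|c" = 1 / 4, "b|d" = 1 / 4, "c|d" = 1 / 3)
  )
})

test_that("cer is uniform when all degrees are equidistant from the mean", {
  d <- edge_weights(toy_fixture("path4"), "cer")
  expect_equal(d$weight, rep(1 / 3, 3))
})

test_that("rnber multiplies injected node values; seeded draws reproduce", {
  d <- edge_weights(kite, "rnber",
                    rnber_values = c(a = 0.5, b = 0.2, c = 1, d = 1))
  w <- stats::setNames(d$weight, kite_keys(d))
  # raw weights: ab = 0.1, bc = bd = 0.2, cd = 1 -> total 1.5
  expect_equal(unname(w["a|b"]), 0.1 / 1.5)
  expect_equal(unname(w["c|d"]), 1 / 1.5)

  d1 <- withr::with_seed(9, edge_weights(kite, "rnber"))
  d2 <- withr::with_seed(9, edge_weights(kite, "rnber"))
  expect_identical(d1$weight, d2$weight)
  expect_false(identical(d1$weight,
                         withr::with_seed(10, edge_weights(kite, "rnber"))$weight))

  unit <- edge_weights(kite, "rnber", rnber_values = rep(1, 4))
  expect_equal(unit$weight, rep(1 / 4, 4))
})

test_that("rwer matches a power-iteration PageRank oracle", {
  pr <- oracle_pagerank(kite)
  names(pr) <- igraph::V(kite)$name
  el <- igraph::as_edgelist(kite)
  raw <- pr[el[, 1]] + pr[el[, 2]]
  d <- edge_weights(kite, "rwer")
  expect_equal(d$weight, unname(raw / sum(raw)), tolerance = 1e-10)
  w <- stats::setNames(d$weight, kite_keys(d))
  expect_equal(unname(w["b|c"]), unname(w["b|d"]), tolerance = 1e-12)
  expect_lt(w["a|b"], w["b|c"])
})

test_that("every scheme is normalised, supported on the edge set, and uniform on regular graphs", {
  graphs <- list(kite = kite, cycle6 = toy_fixture("cycle6"),
                 star4 = toy_fixture("star4"),
                 er = generate_erdos_renyi(40, 0.2, seed = 5))
  for (g in graphs) {
    for (m in removal_methods()) {
      d <- withr::with_seed(1, edge_weights(g, m))
      expect_equal(sum(d$weight), 1, tolerance = 1e-12)
      expect_true(all(d$weight >= 0))
      expect_setequal(kite_keys(d),
                      kite_keys(as.data.frame(igraph::as_edgelist(g)) |>
                                  stats::setNames(c("from", "to"))))
    }
  }
  # regular graphs: all degree-derived schemes collapse to uniform
  ring <- toy_fixture("cycle6")
  for (m in c("rer", "hcer", "lcer", "cer", "rwer")) {
    expect_equal(edge_weights(ring, m)$weight, rep(1 / 6, 6),
                 tolerance = 1e-10, label = m)
  }
  # star edges are symmetric under hcer and rwer too
  expect_equal(edge_weights(toy_fixture("star4"), "hcer")$weight, rep(1 / 4, 4))
  expect_equal(edge_weights(toy_fixture("star4"), "rwer")$weight,
               rep(1 / 4, 4), tolerance = 1e-10)
})

test_that("single-edge draw frequencies match scheme weights (chi-squared)", {
  n_trials <- 20000
  for (m in c("hcer", "lcer", "cer")) {
    d <- edge_weights(kite, m)
    draws <- withr::with_seed(33, {
      replicate(n_trials, {
        s <- sample_removal_set(kite, d, fraction = 0.25)  # 1 of 4 edges
        kite_keys(s)
      })
    })
    obs <- table(factor(draws, levels = kite_keys(d)))
    p <- stats::chisq.test(obs, p = d$weight)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("without-replacement inclusion probabilities match brute-force enumeration", {
  d <- edge_weights(kite, "hcer")
  expected <- oracle_inclusion_probs(d$weight, k = 2)
  n_trials <- 100000
  counts <- stats::setNames(numeric(4), kite_keys(d))
  withr::with_seed(101, {
    for (i in seq_len(n_trials)) {
      s <- sample_removal_set(kite, d, fraction = 0.5)
      counts[kite_keys(s)] <- counts[kite_keys(s)] + 1
    }
  })
  expect_equal(unname(counts / n_trials), expected, tolerance = 0.01)
  # inclusion probabilities of k draws sum to k
  expect_equal(sum(expected), 2, tolerance = 1e-12)
})

test_that("removal-set size follows round-half-to-even and the edge cases", {
  expect_equal(nrow(sample_removal_set(kite, "rer", 0)), 0)
  full <- withr::with_seed(2, sample_removal_set(kite, "rer", 1))
  expect_equal(nrow(full), 4)
  expect_setequal(kite_keys(full), kite_keys(edge_weights(kite, "rer")))
  # 0.5 * 6 edges of cycle6 = 3; 0.25 * 6 = 1.5 rounds to 2 (half to even)
  expect_equal(nrow(withr::with_seed(3,
    sample_removal_set(toy_fixture("cycle6"), "rer", 0.25))), 2)
  expect_error(sample_removal_set(kite, "rer", 1.5), "fraction")
})

test_that("sampling is reproducible and the every-k policy recomputes weights", {
  g <- generate_erdos_renyi(60, 0.15, seed = 8)
  a <- withr::with_seed(5, sample_removal_set(g, "hcer", 0.4))
  b <- withr::with_seed(5, sample_removal_set(g, "hcer", 0.4))
  expect_identical(a, b)
  ek <- withr::with_seed(5, sample_removal_set(g, "hcer", 0.4,
                                               policy = "every-k", refresh_k = 10))
  expect_equal(nrow(ek), nrow(a))
  expect_false(anyDuplicated(kite_keys(ek)) > 0)
  # removed edges all existed in g
  expect_true(all(igraph::get_edge_ids(g, rbind(ek$from, ek$to)) > 0))
})

test_that("apply_removal validates membership and preserves the input", {
  expect_error(apply_removal(kite, tibble::tibble(from = "a", to = "z")),
               "not present")
  red <- apply_removal(kite, sample_removal_set(kite, "rer", 0))
  expect_equal(igraph::ecount(red), 4)
  empty <- apply_removal(kite, edge_tibble_all <- tibble::tibble(
    from = c("a", "b", "b", "c"), to = c("b", "c", "d", "d")))
  expect_equal(igraph::ecount(empty), 0)
  expect_equal(igraph::vcount(empty), 4)
})

test_that("empty edge sets are rejected by every weighting scheme", {
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  for (m in removal_methods()) {
    expect_error(withr::with_seed(1, edge_weights(g0, m)), "empty edge set")
  }
})
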