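test_that("spearman_rho matches hand computations and the counting-rank oracle", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # tie case: ranks of x are (1, 2.5, 2.5, 4) -> 4.5 / sqrt(22.5)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 2, 3, 4)),
               4.5 / sqrt(22.5), tolerance = 1e-9)
  expect_equal(4.5 / sqrt(22.5), 0.948683, tolerance = 1e-6)

  withr::with_seed(55, {
    for (i in 1:25) {
      n <- sample(3:6, 1)
      x <- sample(1:4, n, replace = TRUE)
      y <- stats::rnorm(n)
      if (stats::sd(x) == 0) next
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
      expect_equal(spearman_rho(x, y),
                   suppressWarnings(stats::cor(x, y, method = "spearman")),
                   tolerance = 1e-12)
    }
  })
})

test_that("spearman_rho is NA for constant vectors, errors on length mismatch", {
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(spearman_rho(c(1, 2, 3), c(2, 2, 2))))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("rho is exactly 1 at removal fraction zero for every method and measure", {
  g <- generate_erdos_renyi(40, 0.2, seed = 2)
  res <- robustness_run(g, methods = removal_methods(),
                        measures = centrality_measures(),
                        fractions = 0, replicates = 1, master_seed = 3)
  expect_equal(res$rho, rep(1, nrow(res)))
})

test_that("robustness runs are deterministic and bounded", {
  g <- generate_erdos_renyi(50, 0.2, seed = 9)
  a <- robustness_run(g, methods = c("rer", "lcer"), measures = "degree",
                      fractions = c(0.2, 0.6), replicates = 3, master_seed = 17)
  b <- robustness_run(g, methods = c("rer", "lcer"), measures = "degree",
                      fractions = c(0.2, 0.6), replicates = 3, master_seed = 17)
  expect_identical(a, b)
  expect_true(all(a$rho >= -1 & a$rho <= 1, na.rm = TRUE))
  c_ <- robustness_run(g, methods = "rer", measures = "degree",
                       fractions = c(0.2, 0.6), replicates = 3, master_seed = 18)
  expect_false(identical(a$rho[a$method == "rer"], c_$rho))
})

test_that("the stored mean equals the mean of stored replicates (complete graph contract)", {
  k30 <- igraph::make_full_graph(30)
  igraph::V(k30)$name <- paste0("v", 1:30)
  curve <- robustness_curve(k30, "rer", "degree", fractions = c(0.3, 0.7),
                            replicates = 4, master_seed = 5)
  expect_true(all(curve$rho >= -1 & curve$rho <= 1, na.rm = TRUE))
  td <- tidy(curve)
  for (f in td$fraction) {
    reps <- curve$rho[curve$fraction == f]
    expect_equal(td$mean_rho[td$fraction == f], mean(reps, na.rm = TRUE))
  }
})

test_that("degree robustness declines with the removal fraction on ER graphs", {
  g <- generate_erdos_renyi(200, 0.1, seed = 31)
  res <- summarise_robustness(
    robustness_run(g, methods = "rer", measures = "degree",
                   fractions = c(0.1, 0.9), replicates = 20, master_seed = 7))
  expect_lt(res$mean_rho[res$fraction == 0.9],
            res$mean_rho[res$fraction == 0.1])
})

test_that("cumulative mode removes nested edge sets and still ends at the target count", {
  g <- generate_erdos_renyi(80, 0.15, seed = 12)
  res <- robustness_run(g, methods = "rer", measures = "degree",
                        fractions = c(0.2, 0.5, 0.8), replicates = 2,
                        master_seed = 4, cumulative = TRUE)
  expect_equal(nrow(res), 6)
  expect_true(all(res$rho >= -1 & res$rho <= 1, na.rm = TRUE))
})

test_that("robustness_matrix has one row per cell with values in range", {
  g <- generate_erdos_renyi(60, 0.15, seed = 3)
  mat <- robustness_matrix(list(er = g), methods = c("rer", "lcer"),
                           measures = c("degree", "pagerank"),
                           fraction = 0.3, replicates = 2, master_seed = 1)
  expect_equal(nrow(mat), 4)
  expect_true(all(mat$mean_rho >= -1 & mat$mean_rho <= 1))
  expect_error(robustness_matrix(list(er = g), fraction = 0), "in \\(0, 1\\)")
})

test_that("curve objects expose tidy/glance/autoplot", {
  g <- generate_erdos_renyi(40, 0.2, seed = 2)
  curve <- robustness_curve(g, "hcer", "pagerank", fractions = c(0.2, 0.5),
                            replicates = 2, master_seed = 2)
  td <- tidy(curve)
  expect_named(td, c("network", "method", "measure", "fraction",
                     "mean_rho", "sd_rho", "n_rho"))
  gl <- glance(curve)
  expect_equal(gl$n_fractions, 2)
  p <- ggplot2::autoplot(curve)
  expect_s3_class(p, "ggplot")
})

test_that("inverted distance weighting for cer is far more rank-preserving on scale-free graphs", {
  g <- generate_barabasi_albert(300, 10, seed = 19)
  printed <- summarise_robustness(
    robustness_run(g, methods = "cer", measures = "degree", fractions = 0.9,
                   replicates = 3, master_seed = 2, cer_invert = FALSE))
  inverted <- summarise_robustness(
    robustness_run(g, methods = "cer", measures = "degree", fractions = 0.9,
                   replicates = 3, master_seed = 2, cer_invert = TRUE))
  expect_gt(inverted$mean_rho, printed$mean_rho)
})
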