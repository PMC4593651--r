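test_that("undirected workload and star value match hand-computed motifs", {
  star4 <- planted_neighborhood(4, 0)
  expect_equal(workload_undirected(star4, "hub"), 6)
  expect_equal(star_value_undirected(star4, "hub"), 0.75)
  expect_equal(star_values(star4)$sv[star_values(star4)$vertex != "hub"],
               rep(0, 4))  # degree-1 spokes score 0 by the formula

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(workload_undirected(k5, "a"), 0)
  expect_equal(star_value_undirected(k5, "a"), 0)

  # degree-3 hub with one intra-spoke edge: 3 pairs - 1 adjacent
  g <- network_from_edges(
    data.frame(f = c("h", "h", "h", "s1"), t = c("s1", "s2", "s3", "s2")), quiet = TRUE)
  expect_equal(workload_undirected(g, "h"), 2)
  expect_equal(star_value_undirected(g, "h"), 4 / 9)

  expect_error(workload_undirected(igraph::make_full_graph(3) + 1, 4), "isolated")
})

test_that("directed partition, workload and star value follow the tripartite model", {
  g <- network_from_edges(data.frame(f = c("a", "v", "v", "c"), t = c("v", "b", "c", "v")),
                          directed = TRUE, quiet = TRUE)
  p <- neighborhood_partition(g, "v")
  expect_equal(p$S, "a"); expect_equal(p$T, "b"); expect_equal(p$C, "c")
  expect_equal(p$m, 0)

  # s -> t arc bypasses the hub: m = 1
  g2 <- network_from_edges(
    data.frame(f = c("s", "v", "v", "c", "s"), t = c("v", "t", "c", "v", "t")),
    directed = TRUE, quiet = TRUE)
  expect_equal(neighborhood_partition(g2, "v")$m, 1)

  expect_equal(workload_directed(list(S = 1, T = 1, C = 0, m = 0)), 1)
  expect_equal(workload_directed(list(S = 2, T = 1, C = 1, m = 0)), 5)
  expect_equal(workload_directed(list(S = 0, T = 0, C = 4, m = 6)), 0)

  expect_equal(star_value_directed(list(S = 1, T = 1, C = 0, m = 0)), 0.4)
  expect_equal(star_value_directed(list(S = 0, T = 0, C = 4, m = 0)), 0.75)
  expect_true(is.na(star_value_directed(list(S = 0, T = 0, C = 0, m = 0))))

  # opposite-direction arc t -> s is not counted
  g3 <- network_from_edges(
    data.frame(f = c("s", "v", "t"), t = c("v", "t", "s")),
    directed = TRUE, quiet = TRUE)
  expect_equal(neighborhood_partition(g3, "v")$m, 0)
  expect_equal(workload_directed(neighborhood_partition(g3, "v")), 1)
})

test_that("directed star value on all-reciprocal graphs equals the undirected value", {
  for (s in 1:20) {
    u <- rand_graph(25, 0.15, directed = FALSE, seed = s)
    d <- igraph::as_directed(u, mode = "mutual")
    expect_equal(star_values(d)$sv, star_values(u)$sv, tolerance = 1e-12)
  }
})

test_that("workload agrees with brute-force spoke-pair enumeration", {
  for (s in 1:15) {
    u <- rand_graph(10, 0.35, directed = FALSE, seed = s)
    sv <- star_values(u)
    for (v in igraph::V(u)$name) {
      if (igraph::degree(u, v) == 0) next
      expect_equal(sv$workload[sv$vertex == v], oracle_workload_und(u, v))
    }
    d <- rand_graph(10, 0.3, directed = TRUE, seed = s + 100)
    svd <- star_values(d)
    for (v in igraph::V(d)$name) {
      p <- neighborhood_partition(d, v)
      if (length(c(p$S, p$T, p$C)) == 0) next
      expect_equal(svd$workload[svd$vertex == v], oracle_workload_dir(d, v))
      expect_equal(workload_directed(p), oracle_workload_dir(d, v))
    }
  }
})

test_that("star value is a rescaled complement of local clustering", {
  # SV = (1 - 1/k)(1 - C_local): independent route through igraph transitivity
  g <- rand_graph(60, 0.15, seed = 42)
  k <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  expected <- ifelse(k >= 2, (1 - 1 / k) * (1 - cc), ifelse(k == 1, 0, NA))
  expect_equal(star_values(g)$sv, unname(expected), tolerance = 1e-12)
})

test_that("histograms are normalized with half-open bins and end-bin clipping", {
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- letters[1:4]
  h <- sv_distribution(k4, bins = 20, quiet = TRUE)
  expect_equal(h$freq[1], 1)
  expect_equal(sum(h$freq), 1)

  star <- planted_neighborhood(10, 0)  # hub SV 0.9, leaves 0
  h2 <- sv_distribution(star, bins = 20, quiet = TRUE)
  expect_equal(h2$count[h2$lo <= 0.9 & h2$hi > 0.9], 1)
  expect_equal(h2$count[1], 10)

  # value exactly 1 lands in the last (closed) bin; out-of-range values clip
  expect_equal(sv_distribution(c(1, 1), bins = 10, quiet = TRUE)$count[10], 2)
  expect_message(h3 <- sv_distribution(c(-0.2, 0.5, 1.3, NA), bins = 10),
                 "1 undefined.*2 value")
  expect_equal(h3$count[c(1, 10)], c(1, 1))
  expect_error(sv_distribution(c(NA_real_, NA_real_)), "No defined")
})

test_that("moment statistics use population moments", {
  expect_equal(moment_stats(c(-1, 0, 1))$skewness, 0)
  expect_equal(moment_stats(c(0, 0, 0, 1))$skewness, 2 / sqrt(3), tolerance = 1e-10)
  expect_error(moment_stats(c(2, 2, 2)), "variance")
  expect_error(moment_stats(c(1, 2)), "at least 3")
  mc <- withr::with_seed(9, stats::rnorm(1e5))
  ms <- moment_stats(mc)
  expect_lt(abs(ms$skewness), 0.05)
  expect_lt(abs(ms$kurtosis), 0.1)
  # histogram route: bin midpoints weighted by counts
  h <- sv_distribution(c(0.1, 0.1, 0.9), bins = 10, quiet = TRUE)
  expect_equal(moment_stats(h)$n, 3)
})

test_that("network summaries reproduce exhaustive small-graph values", {
  ring <- igraph::make_ring(5); igraph::V(ring)$name <- letters[1:5]
  s <- summarize_network(ring)
  expect_equal(s$diameter, 2)
  expect_equal(s$cpl, 1.5)
  expect_equal(s$mean_cc, 0)
  expect_equal(s$mean_sv, 0.5)
  expect_equal(s$n_edges_arcs, 10)

  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- letters[1:4]
  s2 <- summarize_network(k4)
  expect_equal(unlist(s2[, c("diameter", "mean_cc", "mean_sv")]),
               c(diameter = 1, mean_cc = 1, mean_sv = 0))
  expect_equal(glance(k4), s2)
})
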