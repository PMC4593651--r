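test_that("degree-preserving rewiring keeps degrees and simplicity", {
  g <- generate_er(60, 0.12, seed = 21)
  r <- ms_rewire(g, rewire_config(seed = 1))
  expect_equal(igraph::degree(r), igraph::degree(g))
  expect_equal(igraph::ecount(r), igraph::ecount(g))
  expect_true(igraph::is_simple(r))

  d <- rand_graph(40, 0.12, directed = TRUE, seed = 22)
  rd <- ms_rewire(d, rewire_config(seed = 2))
  expect_equal(igraph::degree(rd, mode = "in"), igraph::degree(d, mode = "in"))
  expect_equal(igraph::degree(rd, mode = "out"), igraph::degree(d, mode = "out"))
  expect_true(igraph::is_simple(rd))

  # same invariants igraph's own switching preserves (independent engine)
  ri <- withr::with_seed(3, igraph::rewire(g, igraph::keeping_degseq(niter = 1000)))
  expect_equal(sort(igraph::degree(ri)), sort(igraph::degree(r)))

  expect_error(ms_rewire(planted_neighborhood(1, 0)), "at least 2 edges")
})

test_that("a star admits no swap and is returned unchanged with a warning", {
  star <- planted_neighborhood(6, 0)
  expect_warning(r <- ms_rewire(star, rewire_config(seed = 4, attempts_per_edge = 20)),
                 "attempt cap")
  expect_identical(sort(paste(igraph::as_edgelist(r)[, 1], igraph::as_edgelist(r)[, 2])),
                   sort(paste(igraph::as_edgelist(star)[, 1], igraph::as_edgelist(star)[, 2])))
})

test_that("unconstrained rewiring scrambles block structure, block-constrained keeps it", {
  bg <- attributed_block_graph(c(15, 15, 15), 0.5, 0.08, seed = 31)
  before <- block_edge_counts(bg$net, bg$attrs)

  ms <- ms_rewire(bg$net, rewire_config(seed = 5))
  expect_false(identical(block_edge_counts(ms, bg$attrs), before))

  bms <- bms_rewire(bg$net, bg$attrs, rewire_config(seed = 6))
  expect_identical(block_edge_counts(bms, bg$attrs), before)
  expect_equal(igraph::degree(bms), igraph::degree(bg$net))
  expect_true(igraph::is_simple(bms))

  # per-vertex per-block degree is invariant under block-constrained swaps
  codes <- bg$attrs$code[match(igraph::V(bg$net)$name, bg$attrs$vertex)]
  block_deg <- function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    tab <- table(factor(c(el[, 1], el[, 2]), levels = seq_along(codes)),
                 factor(codes[c(el[, 2], el[, 1])], levels = 1:3))
    unclass(tab)
  }
  expect_equal(block_deg(bms), block_deg(bg$net))

  # directed variant: ordered block matrix preserved
  dbg <- attributed_block_graph(c(10, 10), 0.4, 0.1, directed = TRUE, seed = 32)
  dbms <- bms_rewire(dbg$net, dbg$attrs, rewire_config(seed = 7))
  expect_identical(block_edge_counts(dbms, dbg$attrs),
                   block_edge_counts(dbg$net, dbg$attrs))
  expect_equal(igraph::degree(dbms, mode = "out"), igraph::degree(dbg$net, mode = "out"))
  expect_equal(igraph::degree(dbms, mode = "in"), igraph::degree(dbg$net, mode = "in"))
})

test_that("two intra-group edges never swap into cross-group edges", {
  # two groups joined by no edges at all: every rewire stays within a group
  bg <- attributed_block_graph(c(8, 8), 0.7, 0, seed = 33)
  codes <- bg$attrs$code[match(igraph::V(bg$net)$name, bg$attrs$vertex)]
  for (s in 1:10) {
    r <- suppressWarnings(bms_rewire(bg$net, bg$attrs, rewire_config(seed = s)))
    el <- igraph::as_edgelist(r, names = FALSE)
    expect_true(all(codes[el[, 1]] == codes[el[, 2]]))
  }
})

test_that("the isomorphic null preserves topology exactly but scrambles attributes", {
  g <- generate_er(40, 0.15, seed = 41)
  iso <- iso_null(g, cfg = rewire_config(seed = 8))
  expect_equal(sort(star_values(iso$net)$sv), sort(star_values(g)$sv))
  expect_equal(sort(unname(igraph::degree(iso$net))), sort(unname(igraph::degree(g))))
  expect_equal(summarize_network(iso$net)[, c("diameter", "cpl", "mean_cc", "mean_sv")],
               summarize_network(g)[, c("diameter", "cpl", "mean_cc", "mean_sv")])

  # the attribute-topology pairing is randomized: disparity profile moves
  bg <- attributed_block_graph(c(12, 12, 12), 0.5, 0.05, seed = 42)
  iso2 <- iso_null(bg$net, bg$attrs, rewire_config(seed = 9))
  p0 <- disparity_profile(bg$net, bg$attrs)
  p1 <- disparity_profile(iso2$net, iso2$attrs)
  expect_false(isTRUE(all.equal(p0, p1)))
})

test_that("seeded rewiring is reproducible and ensembles use consecutive seeds", {
  g <- generate_er(40, 0.15, seed = 51)
  a <- ms_rewire(g, rewire_config(seed = 10))
  b <- ms_rewire(g, rewire_config(seed = 10))
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))

  ens <- null_ensemble(g, "ms", reps = 3, seed = 10)
  expect_identical(igraph::as_edgelist(ens[[1]]), igraph::as_edgelist(a))
  expect_false(identical(igraph::as_edgelist(ens[[2]]), igraph::as_edgelist(ens[[1]])))
  expect_error(null_ensemble(g, "bms"), "attribute map")
})

test_that("degree-preserving nulls of a cliquey fixture shift the SV distribution", {
  # planted cliques give the original a clique-like mode that MS destroys
  cliques <- lapply(1:6, function(i) {
    g <- igraph::make_full_graph(6)
    igraph::V(g)$name <- sprintf("c%d_%d", i, 1:6)
    g
  })
  spine <- network_from_edges(
    data.frame(f = sprintf("c%d_1", 1:5), t = sprintf("c%d_1", 2:6)), quiet = TRUE)
  fix <- igraph::union(igraph::disjoint_union(cliques[[1]], cliques[[2]], cliques[[3]],
                                              cliques[[4]], cliques[[5]], cliques[[6]]),
                       spine)
  nulls <- null_ensemble(fix, "ms", reps = 20, seed = 60)
  h0 <- sv_distribution(fix, bins = 10, quiet = TRUE)
  h1 <- ensemble_sv_distribution(nulls, bins = 10)
  expect_gt(max(abs(h0$freq - h1$freq)), 0.1)
  null_means <- vapply(nulls, function(g) mean(star_values(g)$sv, na.rm = TRUE), numeric(1))
  expect_gt(mean(null_means), mean(star_values(fix)$sv, na.rm = TRUE))
})
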