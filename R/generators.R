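.name_vertices <- function(g, prefix = "v") {
  n <- igraph::vcount(g)
  igraph::V(g)$name <- sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
  g
}

#' Seeded random-graph generators
#'
#' Thin seeded wrappers over \pkg{igraph}'s generators, returning simple
#' named graphs: `generate_er()` draws each vertex pair independently with
#' probability `p` (Erdos-Renyi G(n, p)); `generate_ba()` grows a
#' preferential-attachment graph adding `edges_per_step` edges per new
#' vertex (Barabasi-Albert); `generate_ws()` rewires each edge of a ring
#' lattice with `neighbors` neighbours on each side independently with
#' probability `p_rewire` (Watts-Strogatz), then removes any multi-edges.
#'
#' @param n Number of vertices (>= 3).
#' @param p Edge probability for ER.
#' @param seed Optional RNG seed for reproducibility.
#' @return An undirected simple `igraph` network with vertex names
#'   `v001, v002, ...`.
#' @examples
#' g <- generate_er(50, 0.1, seed = 1)
#' igraph::ecount(g)
#' @export
generate_er <- function(n, p, seed = NULL) {
  stopifnot(n >= 3, p >= 0, p <= 1)
  .with_seed(seed, .name_vertices(igraph::sample_gnp(n, p)))
}

#' @rdname generate_er
#' @param edges_per_step Edges added per new vertex (BA); must be `< n`.
#' @export
generate_ba <- function(n, edges_per_step, seed = NULL) {
  stopifnot(n >= 3)
  if (edges_per_step >= n) abort("BA edges_per_step must be smaller than n.")
  .with_seed(seed, .name_vertices(
    igraph::sample_pa(n, m = edges_per_step, directed = FALSE)))
}

#' @rdname generate_er
#' @param neighbors Lattice neighbours on each side (WS); lattice degree is
#'   `2 * neighbors`.
#' @param p_rewire Per-edge rewiring probability (WS).
#' @export
generate_ws <- function(n, neighbors, p_rewire, seed = NULL) {
  stopifnot(n >= 3, neighbors >= 1, p_rewire >= 0, p_rewire <= 1)
  .with_seed(seed, .name_vertices(igraph::simplify(
    igraph::sample_smallworld(1, n, neighbors, p_rewire))))
}

#' ER calibration matched to the macaque undirected connectome
#'
#' The density-matched Erdos-Renyi benchmark uses `n = 351` vertices and
#' edge probability `p = 10194 / (351 * 350)`, i.e. the symmetric-arc
#' density of the undirected macaque network (10194 arcs = 5097 unordered
#' edges over 351 areas). With this `p` the expected ER clustering
#' coefficient equals the benchmark value 0.083.
#'
#' @return A list with elements `n` and `p`.
#' @export
macaque_er_spec <- function() list(n = 351L, p = 10194 / (351 * 350))

#' Planted hub-and-spokes neighbourhood
#'
#' A hub joined to `k` spokes with exactly `m` intra-spoke edges chosen
#' uniformly at random, so the hub's star value is `1 - (2m + k)/k^2` by
#' construction: `m = 0` gives a pure star (`SV = 1 - 1/k`), the maximum
#' `m = k(k-1)/2` gives a clique hub (`SV = 0`).
#'
#' @param k Number of spokes (>= 1).
#' @param m Number of intra-spoke edges, in `0 .. k(k-1)/2`.
#' @param seed Optional RNG seed.
#' @return An undirected `igraph`; the hub is the vertex named `"hub"`.
#' @export
planted_neighborhood <- function(k, m, seed = NULL) {
  stopifnot(k >= 1)
  if (m < 0 || m > k * (k - 1) / 2) {
    abort(sprintf("m must lie in 0..%d for k = %d spokes.", (k * (k - 1)) %/% 2, k))
  }
  spokes <- sprintf("s%0*d", nchar(k), seq_len(k))
  .with_seed(seed, {
    pairs <- if (k >= 2) t(utils::combn(spokes, 2)) else matrix(character(0), 0, 2)
    pick <- if (m > 0) pairs[sample(nrow(pairs), m), , drop = FALSE] else pairs[0, , drop = FALSE]
    network_from_edges(
      data.frame(from = c(rep("hub", k), pick[, 1]),
                 to = c(spokes, pick[, 2])),
      directed = FALSE, quiet = TRUE
    )
  })
}

#' Attributed stochastic block fixture
#'
#' An ER-style graph with group-dependent edge probabilities: vertex pairs
#' inside a group connect with `p_intra`, pairs across groups with
#' `p_inter`; vertex attributes are the block memberships. Emulates the
#' block structure of a parcellated connectome (dense super-areas, sparser
#' long-distance wiring) for disparity/closure/brokerage and
#' block-constrained-null testing.
#'
#' @param sizes Integer vector of group sizes.
#' @param p_intra,p_inter Within- and between-group edge probabilities.
#' @param directed Generate arcs (each ordered pair independently)?
#' @param seed Optional RNG seed.
#' @param labels Optional group labels (default `"G1"`, `"G2"`, ...).
#' @return A list with elements `net` (`igraph`) and `attrs`
#'   ([attribute_map()]).
#' @export
attributed_block_graph <- function(sizes, p_intra, p_inter, directed = FALSE,
                                   seed = NULL, labels = NULL) {
  stopifnot(all(sizes >= 1), p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1)
  K <- length(sizes)
  labels <- labels %||% sprintf("G%d", seq_len(K))
  n <- sum(sizes)
  grp <- rep(seq_len(K), sizes)
  verts <- sprintf("g%d_%0*d", grp, nchar(max(sizes)),
                   unlist(lapply(sizes, seq_len)))
  .with_seed(seed, {
    idx <- if (directed) {
      cbind(rep(seq_len(n), each = n), rep(seq_len(n), n))
    } else {
      t(utils::combn(n, 2))
    }
    idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
    pvec <- ifelse(grp[idx[, 1]] == grp[idx[, 2]], p_intra, p_inter)
    keep <- stats::runif(nrow(idx)) < pvec
    if (!any(keep)) abort("Block fixture came out empty; raise the densities.")
    net <- network_from_edges(
      data.frame(from = verts[idx[keep, 1]], to = verts[idx[keep, 2]]),
      directed = directed, quiet = TRUE
    )
    # attribute rows only for vertices that received an edge
    present <- igraph::V(net)$name
    attrs <- attribute_map(
      data.frame(vertex = verts, label = labels[grp])[verts %in% present, ],
      net, label_order = labels
    )
    list(net = net, attrs = attrs)
  })
}
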