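#' Configuration for edge-swap randomization
#'
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @param swaps_per_edge Target number of successful double-edge swaps per
#'   edge (default 10, common practice for degree-preserving
#'   randomization).
#' @param attempts_per_edge Cap on attempted swaps per edge before giving
#'   up with a warning.
#' @return A list of class `rewire_config`.
#' @export
rewire_config <- function(seed = NULL, swaps_per_edge = 10, attempts_per_edge = 100) {
  stopifnot(swaps_per_edge > 0, attempts_per_edge > 0)
  structure(list(seed = seed, swaps_per_edge = swaps_per_edge,
                 attempts_per_edge = attempts_per_edge),
            class = "rewire_config")
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Isomorphic null model
#'
#' Relabels the vertices by a uniformly random permutation. The topology is
#' exactly isomorphic to the original — every purely structural quantity
#' (degree distribution, diameter, star-value multiset, ...) is preserved —
#' but attributes stay attached to the *names*, so the pairing between
#' attribute space and topology is randomized.
#'
#' @param net An `igraph` network.
#' @param attrs Optional [attribute_map()]; returned unchanged (the
#'   randomization lives in the relabeled topology).
#' @param cfg A [rewire_config()] (only its `seed` is used).
#' @return A list with elements `net` (relabeled network) and `attrs`.
#' @export
iso_null <- function(net, attrs = NULL, cfg = rewire_config()) {
  .with_seed(cfg$seed, {
    names_old <- igraph::V(net)$name
    perm <- sample(names_old)
    g2 <- net
    igraph::V(g2)$name <- perm
    list(net = g2, attrs = attrs)
  })
}

# Double-edge-swap engine shared by ms_rewire and bms_rewire.
# el: m x 2 integer matrix; groups: per-vertex codes or NULL (unconstrained).
# Returns list(el, achieved, target, capped_blocks).
.swap_engine <- function(el, directed, groups, swaps_per_edge, attempts_per_edge) {
  m <- nrow(el)
  ekey <- function(a, b) {
    if (directed) paste0(a, ".", b) else paste0(pmin(a, b), ".", pmax(a, b))
  }
  exists_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(ekey(el[i, 1], el[i, 2]), TRUE, envir = exists_env)

  if (is.null(groups)) {
    block_id <- rep("all", m)
    bip <- c(all = FALSE)
  } else {
    g1 <- groups[el[, 1]]; g2 <- groups[el[, 2]]
    if (directed) {
      block_id <- paste0(g1, ">", g2)
      bip <- setNames(rep(FALSE, length(unique(block_id))), unique(block_id))
    } else {
      block_id <- paste0(pmin(g1, g2), "~", pmax(g1, g2))
      # orient inter-group edges low-group-first so swaps keep endpoints in
      # their groups (bipartite-safe)
      inter <- g1 != g2
      flip <- inter & g1 > g2
      el[flip, ] <- el[flip, 2:1]
      bip <- vapply(split(inter, block_id), any, logical(1))
    }
  }

  capped <- character(0)
  achieved_total <- 0; target_total <- 0
  for (bl in sort(unique(block_id))) {
    rows <- which(block_id == bl)
    mb <- length(rows)
    if (mb < 2) next
    target <- ceiling(swaps_per_edge * mb)
    cap <- ceiling(attempts_per_edge * mb)
    target_total <- target_total + target
    done <- 0; tries <- 0
    bipartite <- isTRUE(bip[[bl]])
    while (done < target && tries < cap) {
      tries <- tries + 1
      ij <- sample(mb, 2)
      i <- rows[ij[1]]; j <- rows[ij[2]]
      a <- el[i, 1]; b <- el[i, 2]; c <- el[j, 1]; d <- el[j, 2]
      if (!directed && !bipartite && stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      if (a == d || c == b) next
      k1 <- ekey(a, d); k2 <- ekey(c, b)
      if (k1 == k2) next
      if (exists(k1, envir = exists_env) || exists(k2, envir = exists_env)) next
      rm(list = c(ekey(a, b), ekey(c, d)), envir = exists_env)
      assign(k1, TRUE, envir = exists_env)
      assign(k2, TRUE, envir = exists_env)
      el[i, ] <- c(a, d)
      el[j, ] <- c(c, b)
      done <- done + 1
    }
    achieved_total <- achieved_total + done
    if (done < target) capped <- c(capped, sprintf("%s (%d/%d)", bl, done, target))
  }
  list(el = el, achieved = achieved_total, target = target_total, capped = capped)
}

.rebuild <- function(net, el) {
  verts <- igraph::V(net)$name
  igraph::graph_from_data_frame(
    data.frame(from = verts[el[, 1]], to = verts[el[, 2]], stringsAsFactors = FALSE),
    directed = igraph::is_directed(net), vertices = verts
  )
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes the network by repeated double-edge swaps
#' `(a,b),(c,d) -> (a,d),(c,b)`, rejecting any swap that would create a
#' self-loop or duplicate edge. Every vertex keeps its degree exactly (its
#' in- and out-degree separately on directed networks) and the edge count
#' is unchanged, but all other structure — including the block structure of
#' any vertex attribute — is randomized. Runs until `swaps_per_edge * m`
#' successful swaps or the attempt cap, whichever comes first (a warning
#' reports the achieved count if capped; e.g. a star admits no valid swap
#' at all and is returned unchanged).
#'
#' @param net An `igraph` network with at least 2 edges.
#' @param cfg A [rewire_config()].
#' @return A rewired `igraph` network on the same vertices.
#' @export
ms_rewire <- function(net, cfg = rewire_config()) {
  if (igraph::ecount(net) < 2) abort("Rewiring needs at least 2 edges.")
  .with_seed(cfg$seed, {
    el <- matrix(as.integer(igraph::as_edgelist(net, names = FALSE)), ncol = 2)
    res <- .swap_engine(el, igraph::is_directed(net), groups = NULL,
                        cfg$swaps_per_edge, cfg$attempts_per_edge)
    if (length(res$capped) > 0) {
      warn(sprintf("ms_rewire: attempt cap reached with %d of %d target swaps done.",
                   res$achieved, res$target))
    }
    .rebuild(net, res$el)
  })
}

#' Block-constrained degree-preserving rewiring
#'
#' Like [ms_rewire()], but swaps are confined to edges of the same block —
#' the (unordered) pair of group codes of an edge's endpoints — and
#' inter-group swaps keep each endpoint in its own group. Consequently the
#' degree sequence, the per-block edge-count matrix, and every vertex's
#' per-block degree are all preserved exactly; only the wiring inside each
#' block is randomized. This is the null model that keeps both the
#' attribute space and the sparsity of every intra- and inter-group
#' subnetwork.
#'
#' @param net An `igraph` network.
#' @param attrs A [attribute_map()] covering `net`.
#' @param cfg A [rewire_config()].
#' @return A rewired `igraph` network.
#' @export
bms_rewire <- function(net, attrs, cfg = rewire_config()) {
  if (igraph::ecount(net) < 2) abort("Rewiring needs at least 2 edges.")
  codes <- attr_codes(attrs, net)
  .with_seed(cfg$seed, {
    el <- matrix(as.integer(igraph::as_edgelist(net, names = FALSE)), ncol = 2)
    res <- .swap_engine(el, igraph::is_directed(net), groups = codes,
                        cfg$swaps_per_edge, cfg$attempts_per_edge)
    if (length(res$capped) > 0) {
      warn(sprintf("bms_rewire: attempt cap reached in block(s) %s.",
                   paste(res$capped, collapse = ", ")))
    }
    .rebuild(net, res$el)
  })
}

#' Per-block edge-count matrix
#'
#' Number of edges between every (unordered) pair of groups; the invariant
#' that [bms_rewire()] preserves and [ms_rewire()] destroys.
#'
#' @inheritParams bms_rewire
#' @return A K x K matrix (upper triangle + diagonal for undirected
#'   networks; full matrix for directed).
#' @export
block_edge_counts <- function(net, attrs) {
  codes <- attr_codes(attrs, net)
  K <- length(attr(attrs, "labels"))
  el <- igraph::as_edgelist(net, names = FALSE)
  g1 <- codes[el[, 1]]; g2 <- codes[el[, 2]]
  m <- matrix(0L, K, K, dimnames = list(attr(attrs, "labels"), attr(attrs, "labels")))
  if (!igraph::is_directed(net)) {
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    for (i in seq_along(lo)) m[lo[i], hi[i]] <- m[lo[i], hi[i]] + 1L
  } else {
    for (i in seq_along(g1)) m[g1[i], g2[i]] <- m[g1[i], g2[i]] + 1L
  }
  m
}

#' Ensemble of null-model replicates
#'
#' Generates `reps` independent replicates of a null model with seeds
#' `seed + 0 .. seed + reps - 1`, so ensembles are reproducible and
#' extensible.
#'
#' @param net An `igraph` network.
#' @param model One of `"ms"`, `"bms"`, `"iso"`.
#' @param attrs Attribute map (required for `"bms"`, optional for
#'   `"iso"`).
#' @param reps Number of replicates (default 20).
#' @param seed Base seed.
#' @param cfg A [rewire_config()] (its `seed` is overridden per replicate).
#' @return A list of `igraph` networks (for `"iso"`, each element is the
#'   relabeled network; attributes are unchanged by construction).
#' @export
null_ensemble <- function(net, model = c("ms", "bms", "iso"), attrs = NULL,
                          reps = 20, seed = 1, cfg = rewire_config()) {
  model <- match.arg(model)
  if (model == "bms" && is.null(attrs)) abort("bms needs an attribute map.")
  lapply(seq_len(reps) - 1L, function(i) {
    cfg$seed <- seed + i
    switch(model,
           ms = ms_rewire(net, cfg),
           bms = bms_rewire(net, attrs, cfg),
           iso = iso_null(net, attrs, cfg)$net)
  })
}
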