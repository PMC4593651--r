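# Brute-force oracles: independent enumeration routes used to validate the
# vectorized implementations on small graphs.

# Named random (di)graph; regenerates until at least one edge exists.
rand_graph <- function(n, p, directed = FALSE, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p, directed = directed)
      if (igraph::ecount(g) > 0) break
    }
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g
  })
}

# Undirected workload: count non-adjacent spoke pairs one by one.
oracle_workload_und <- function(g, v) {
  nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
  if (length(nb) < 2) return(0)
  pairs <- utils::combn(nb, 2)
  sum(vapply(seq_len(ncol(pairs)), function(i) {
    !igraph::are_adjacent(g, pairs[1, i], pairs[2, i])
  }, logical(1)))
}

# Directed workload: pair-by-pair mediated-communication units. Ordered
# source->target pairs contribute 1 unless the direct arc exists; a
# reciprocal spoke pair is one unordered unit, fully served only when both
# direct arcs exist.
oracle_workload_dir <- function(g, v) {
  vn <- igraph::V(g)$name
  inn <- vn[igraph::neighbors(g, v, mode = "in")]
  out <- vn[igraph::neighbors(g, v, mode = "out")]
  C <- intersect(inn, out); S <- setdiff(inn, C); T <- setdiff(out, C)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  L <- 0
  for (s in S) for (t in T) L <- L + 1 - A[s, t]
  for (s in S) for (cc in C) L <- L + 1 - A[s, cc]
  for (cc in C) for (t in T) L <- L + 1 - A[cc, t]
  if (length(C) >= 2) {
    prs <- utils::combn(C, 2)
    for (i in seq_len(ncol(prs))) {
      L <- L + 1 - (A[prs[1, i], prs[2, i]] + A[prs[2, i], prs[1, i]]) / 2
    }
  }
  L
}

# WCC by exhaustive triple enumeration.
oracle_wcc <- function(g, attrs, code) {
  vn <- igraph::V(g)$name
  codes <- attrs$code[match(vn, attrs$vertex)]
  members <- vn[codes == code]
  open <- 0; closed <- 0
  if (length(members) >= 2) {
    prs <- utils::combn(members, 2)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1, i]; b <- prs[2, i]
      if (igraph::are_adjacent(g, a, b)) next
      hubs <- intersect(igraph::V(g)$name[igraph::neighbors(g, a)],
                        igraph::V(g)$name[igraph::neighbors(g, b)])
      if (length(hubs) == 0) next
      open <- open + 1
      if (any(codes[match(hubs, vn)] == code)) closed <- closed + 1
    }
  }
  list(open = open, closed = closed, wcc = if (open > 0) closed / open else 1)
}

# Gould-Fernandez counts for one broker by O(n^2) loops over (s, t).
oracle_brokerage <- function(g, attrs, b) {
  vn <- igraph::V(g)$name
  codes <- attrs$code[match(vn, attrs$vertex)]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  counts <- c(coordinator = 0L, gatekeeper = 0L, representative = 0L,
              consultant = 0L, liaison = 0L)
  ab <- codes[match(b, vn)]
  for (s in vn) for (t in vn) {
    if (s == t || s == b || t == b) next
    if (A[s, b] == 0 || A[b, t] == 0 || A[s, t] != 0) next
    as <- codes[match(s, vn)]; at <- codes[match(t, vn)]
    role <- if (as == ab && ab == at) "coordinator"
      else if (as != ab && ab == at) "gatekeeper"
      else if (as == ab && at != ab) "representative"
      else if (as == at && ab != as) "consultant"
      else "liaison"
    counts[role] <- counts[role] + 1L
  }
  counts
}

# Random group assignment for a named graph.
rand_attrs <- function(g, K, seed = 1) {
  withr::with_seed(seed, {
    vn <- sort(igraph::V(g)$name)
    attribute_map(
      data.frame(vertex = vn,
                 label = sprintf("G%d", sample(K, length(vn), replace = TRUE))),
      g, label_order = sprintf("G%d", seq_len(K)))
  })
}
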