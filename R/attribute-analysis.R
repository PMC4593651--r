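#' Attribute disparity of a local subnetwork
#'
#' The disparity of a hub is the number of distinct spoke group codes that
#' differ from the hub's own code: 0 means the whole neighbourhood lies in
#' the hub's group, `K - 1` means the spokes span every other group.
#' Disparity, like the workload closure analyses, is defined on the
#' undirected network.
#'
#' @param net An undirected `igraph` network.
#' @param attrs A [attribute_map()] tibble covering `net`.
#' @param v A vertex name.
#' @return Integer disparity in `0..K-1`.
#' @export
disparity <- function(net, attrs, v) {
  .check_undirected(net, "disparity")
  nb <- igraph::neighbors(net, v)
  if (length(nb) == 0) abort("Disparity is undefined for an isolated vertex.")
  codes <- attr_codes(attrs, net)
  idx <- match(if (is.character(v)) v else igraph::V(net)$name[v], igraph::V(net)$name)
  length(setdiff(codes[as.integer(nb)], codes[idx]))
}

.check_undirected <- function(net, what) {
  if (igraph::is_directed(net)) {
    abort(sprintf("%s is defined on the undirected network; apply to_undirected() first.", what))
  }
}

#' Per-vertex disparity table
#'
#' Disparity, degree, group code and star value of every non-isolated
#' vertex.
#'
#' @inheritParams disparity
#' @return A tibble with columns `vertex`, `code`, `label`, `degree`,
#'   `disparity`, `sv` (isolated vertices are dropped).
#' @export
disparity_table <- function(net, attrs) {
  .check_undirected(net, "disparity")
  codes <- attr_codes(attrs, net)
  verts <- igraph::V(net)$name
  deg <- igraph::degree(net)
  sv <- star_values(net)
  nbl <- igraph::adjacent_vertices(net, igraph::V(net))
  disp <- vapply(seq_along(verts), function(i) {
    if (deg[i] == 0) return(NA_integer_)
    length(setdiff(codes[as.integer(nbl[[i]])], codes[i]))
  }, integer(1))
  out <- tibble(vertex = verts, code = codes,
                label = attr(attrs, "labels")[codes],
                degree = as.integer(deg), disparity = disp) |>
    inner_join(sv[, c("vertex", "sv")], by = "vertex") |>
    filter(!is.na(.data$disparity)) |>
    arrange(.data$vertex)
  out
}

#' Disparity profile of a network
#'
#' Aggregates the per-vertex disparity table by disparity value: number and
#' normalized fraction of local subnetworks, their mean star value and mean
#' hub degree. In the macaque connectome mean star value rises with
#' disparity — star-like subnetworks tend to span super-areas while cliques
#' sit inside one.
#'
#' @inheritParams disparity
#' @return A tibble of class `disparity_profile` with columns `disparity`,
#'   `n`, `freq`, `mean_sv`, `mean_degree` (`sum(freq) == 1`).
#' @export
disparity_profile <- function(net, attrs) {
  tab <- disparity_table(net, attrs)
  out <- tab |>
    group_by(.data$disparity) |>
    summarise(n = n(), mean_sv = mean(.data$sv), mean_degree = mean(.data$degree),
              .groups = "drop") |>
    mutate(freq = .data$n / sum(.data$n)) |>
    select("disparity", "n", "freq", "mean_sv", "mean_degree") |>
    arrange(.data$disparity)
  class(out) <- c("disparity_profile", class(out))
  out
}

#' Same-group spoke pairs with an open triad
#'
#' A pair of vertices are spokes if they share at least one common
#' neighbour (a hub, of any group). The open pairs of group `g` are the
#' unordered non-adjacent pairs of `g`-vertices that are spokes of some
#' hub; the pair is workload-closed if at least one of its hubs also lies
#' in `g`.
#'
#' @inheritParams disparity
#' @param g A group code (integer) or group label.
#' @return A tibble with one row per open pair: `a`, `b`, `n_hubs`,
#'   `n_hubs_in_group`, `closed`.
#' @export
open_pairs_in_group <- function(net, attrs, g) {
  .check_undirected(net, "Workload closure")
  code <- .resolve_group(attrs, g)
  codes <- attr_codes(attrs, net)
  verts <- igraph::V(net)$name
  members <- which(codes == code)
  if (length(members) < 2) {
    return(tibble(a = character(), b = character(), n_hubs = integer(),
                  n_hubs_in_group = integer(), closed = logical()))
  }
  nbl <- igraph::adjacent_vertices(net, igraph::V(net))
  nbl <- lapply(nbl, as.integer)
  rows <- list()
  for (ii in seq_along(members)[-length(members)]) {
    i <- members[ii]
    for (j in members[seq_along(members) > ii]) {
      if (j %in% nbl[[i]]) next
      hubs <- intersect(nbl[[i]], nbl[[j]])
      if (length(hubs) == 0) next
      in_g <- sum(codes[hubs] == code)
      rows[[length(rows) + 1L]] <- tibble(
        a = min(verts[i], verts[j]), b = max(verts[i], verts[j]),
        n_hubs = length(hubs), n_hubs_in_group = in_g, closed = in_g > 0
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(a = character(), b = character(), n_hubs = integer(),
                  n_hubs_in_group = integer(), closed = logical()))
  }
  arrange(bind_rows(rows), .data$a, .data$b)
}

.resolve_group <- function(attrs, g) {
  labels <- attr(attrs, "labels")
  if (is.character(g)) {
    code <- match(g, labels)
    if (is.na(code)) abort(sprintf("Unknown group label '%s'.", g))
  } else {
    code <- as.integer(g)
    if (is.na(code) || code < 1 || code > length(labels)) {
      abort(sprintf("Unknown group code %s.", as.character(g)))
    }
  }
  code
}

#' Workload closure coefficient of a group
#'
#' The fraction of a group's open spoke pairs that are closed by a hub of
#' the same group. A closed group (`wcc = 1`) can serve all of its internal
#' 2-hop communication with its own vertices. The record also carries the
#' intra-group density (edges within the group over possible pairs) and the
#' mean local clustering coefficient of the induced subnetwork, the two
#' companions that shape how much workload is available in the first place.
#' A group with no open pairs is vacuously closed: `wcc = 1` with
#' `degenerate = TRUE`.
#'
#' @inheritParams open_pairs_in_group
#' @return A one-row tibble: `code`, `label`, `n_vertices`, `n_open`,
#'   `n_closed`, `wcc`, `degenerate`, `density`, `cc`.
#' @export
wcc <- function(net, attrs, g) {
  code <- .resolve_group(attrs, g)
  pairs <- open_pairs_in_group(net, attrs, code)
  codes <- attr_codes(attrs, net)
  members <- which(codes == code)
  if (length(members) == 0) abort(sprintf("Group %s has no vertices.", as.character(g)))
  sub <- igraph::induced_subgraph(net, members)
  ng <- length(members)
  dens <- if (ng > 1) igraph::ecount(sub) / (ng * (ng - 1) / 2) else NA_real_
  loc <- igraph::transitivity(sub, type = "local", isolates = "NaN")
  cc <- if (any(is.finite(loc))) mean(loc[is.finite(loc)]) else 0
  n_open <- nrow(pairs)
  n_closed <- sum(pairs$closed)
  tibble(
    code = code, label = attr(attrs, "labels")[code], n_vertices = ng,
    n_open = n_open, n_closed = n_closed,
    wcc = if (n_open > 0) n_closed / n_open else 1,
    degenerate = n_open == 0, density = dens, cc = cc
  )
}

#' Workload closure table over all groups
#'
#' [wcc()] applied to every group, sorted by ascending closure so the
#' least self-sufficient group comes first.
#'
#' @inheritParams disparity
#' @return A tibble of class `wcc_tbl`, one row per group.
#' @export
wcc_table <- function(net, attrs) {
  out <- purrr::map_dfr(seq_len(n_groups(attrs)), function(g) wcc(net, attrs, g))
  out <- arrange(out, .data$wcc, .data$label)
  class(out) <- c("wcc_tbl", class(out))
  out
}
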