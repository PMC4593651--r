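#' Communication workload of a hub in an undirected network
#'
#' The local subnetwork of a vertex (the "hub") is the network induced by the
#' hub and its adjacent vertices (the "spokes"). With `k` spokes and `m`
#' edges among them, the hub mediates shortest-path communication for the
#' `k(k-1)/2 - m` non-adjacent spoke pairs; that count is its workload.
#'
#' @param net An undirected `igraph` network.
#' @param v A vertex name (or index).
#' @return Non-negative number of open spoke pairs through `v`.
#' @seealso [star_value_undirected()], [star_values()] for all vertices at once.
#' @export
workload_undirected <- function(net, v) {
  stopifnot(!igraph::is_directed(net))
  k <- unname(igraph::degree(net, v))
  if (k == 0) abort("Workload is undefined for an isolated vertex.")
  nb <- igraph::neighbors(net, v)
  m <- igraph::ecount(igraph::induced_subgraph(net, nb))
  k * (k - 1) / 2 - m
}

#' Star value of a hub in an undirected network
#'
#' Workload normalized by `k^2/2` so that a clique hub scores 0 and a star
#' hub with `k` spokes scores `1 - 1/k`, approaching 1 for large stars:
#' `SV = 2L/k^2 = 1 - (2m + k)/k^2`.
#'
#' @inheritParams workload_undirected
#' @return Star value in `[0, 1)`.
#' @export
star_value_undirected <- function(net, v) {
  k <- unname(igraph::degree(net, v))
  if (k == 0) abort("Star value is undefined for an isolated vertex.")
  2 * workload_undirected(net, v) / k^2
}

#' Directed neighbourhood partition of a hub
#'
#' In a directed network the spokes of a hub split into three disjoint sets:
#' `S` (arc into the hub only), `T` (arc from the hub only) and `C`
#' (reciprocal). Communication flows from the source side `S + C` to the
#' target side `T + C` through the hub. `m` counts the direct source-to-target
#' arcs among the spokes that bypass the hub: arcs `s->t`, `s->c`, `c->t`
#' count one unit each, and an arc between two reciprocal spokes counts one
#' half (so a reciprocally connected `C` pair contributes a full unit,
#' matching the unordered pair it closes). Arcs in the opposite direction
#' (e.g. `t->s`) carry no 2-hop traffic through the hub and are not counted.
#'
#' @param net A directed `igraph` network.
#' @param v A vertex name (or index).
#' @return A list of class `nbhd_partition` with elements `hub`, `S`, `T`,
#'   `C` (character vectors of vertex names) and `m` (possibly
#'   half-integral).
#' @export
neighborhood_partition <- function(net, v) {
  stopifnot(igraph::is_directed(net))
  vn <- if (is.character(v)) v else igraph::V(net)$name[v]
  if (length(vn) != 1 || is.na(vn) || !vn %in% igraph::V(net)$name) {
    abort(sprintf("Vertex '%s' is not in the network.", as.character(v)[1]))
  }
  inn <- igraph::V(net)$name[igraph::neighbors(net, vn, mode = "in")]
  out <- igraph::V(net)$name[igraph::neighbors(net, vn, mode = "out")]
  C <- intersect(inn, out)
  S <- setdiff(inn, C)
  T <- setdiff(out, C)
  p <- list(hub = vn, S = sort(S), T = sort(T), C = sort(C),
            m = .spoke_arc_weight(net, S, T, C))
  class(p) <- "nbhd_partition"
  p
}

# Weighted count of source-side -> target-side arcs among spokes (D5 weights).
.spoke_arc_weight <- function(net, S, T, C) {
  src <- c(S, C); tgt <- c(T, C)
  if (length(src) == 0 || length(tgt) == 0) return(0)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  full <- sum(A[src, tgt, drop = FALSE])
  cc <- if (length(C) > 0) sum(A[C, C, drop = FALSE]) else 0
  full - cc / 2
}

#' Workload of a hub in a directed network
#'
#' Mediated communication units through the hub: every `(s, t)`, `(s, c)` and
#' `(c, t)` ordered source/target pair plus every unordered reciprocal pair,
#' minus the direct spoke-to-spoke arcs `m` (see
#' [neighborhood_partition()]):
#' `L = |S|(|T| + |C|) + |C|(|T| + (|C| - 1)/2) - m`.
#'
#' @param p A `nbhd_partition`, or a list with elements `S`, `T`, `C`
#'   (vectors or counts) and `m`.
#' @return Non-negative workload (may be half-integral).
#' @export
workload_directed <- function(p) {
  s <- .pn(p$S); t <- .pn(p$T); cc <- .pn(p$C)
  s * (t + cc) + cc * (t + (cc - 1) / 2) - p$m
}

.pn <- function(x) if (is.numeric(x) && length(x) == 1) x else length(x)

#' Star value of a hub in a directed network
#'
#' Workload normalized so a directed clique (every source spoke directly
#' reaching every target spoke) scores 0 and large directed stars approach 1.
#' The default denominator convention `"P1"` is
#' `|S|(|T| + |C| + 2)/2 + |T|(|C| + 1) + |C|^2/2`, the unique reading that
#' reduces exactly to the undirected star value when `S = T = 0` (all
#' neighbours reciprocal). Values can marginally exceed 1 for very
#' asymmetric neighbourhoods; they are reported raw and only clipped when
#' binned into histograms.
#'
#' @inheritParams workload_directed
#' @param denom Denominator convention; only `"P1"` is currently defined.
#' @return Star value (nominally in `[0, 1]`); `NA` for an empty
#'   neighbourhood.
#' @export
star_value_directed <- function(p, denom = "P1") {
  denom <- match.arg(denom, "P1")
  s <- .pn(p$S); t <- .pn(p$T); cc <- .pn(p$C)
  d <- s * (t + cc + 2) / 2 + t * (cc + 1) + cc^2 / 2
  if (d == 0) return(NA_real_)
  workload_directed(p) / d
}

#' Per-vertex star-value table
#'
#' Computes the neighbourhood decomposition, workload and star value for
#' every vertex of a network. For undirected networks all spokes are
#' reciprocal (`n_source = n_target = 0`); isolated vertices (and directed
#' vertices with an empty partition) get `NA` star values and are excluded
#' from histograms and means downstream.
#'
#' @param net An `igraph` network, directed or undirected.
#' @param denom Directed denominator convention, see [star_value_directed()].
#' @return A tibble of class `sv_tbl` with columns `vertex`, `n_source`,
#'   `n_target`, `n_reciprocal`, `m`, `workload`, `sv`, ordered by vertex
#'   name.
#' @examples
#' star <- igraph::make_star(5, mode = "undirected", center = 1)
#' igraph::V(star)$name <- letters[1:5]
#' star_values(star)
#' @export
star_values <- function(net, denom = "P1") {
  verts <- igraph::V(net)$name
  ord <- order(verts)
  if (!igraph::is_directed(net)) {
    k <- unname(igraph::degree(net))
    m <- igraph::count_triangles(net)
    L <- k * (k - 1) / 2 - m
    sv <- ifelse(k > 0, 2 * L / pmax(k, 1)^2, NA_real_)
    out <- tibble(vertex = verts, n_source = 0L, n_target = 0L,
                  n_reciprocal = as.integer(k), m = as.numeric(m),
                  workload = ifelse(k > 0, L, NA_real_), sv = sv)
  } else {
    A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
    n <- nrow(A)
    res <- lapply(seq_len(n), function(i) {
      inn <- which(A[, i] != 0)
      out <- which(A[i, ] != 0)
      C <- intersect(inn, out)
      S <- setdiff(inn, C)
      T <- setdiff(out, C)
      src <- c(S, C); tgt <- c(T, C)
      m <- if (length(src) && length(tgt)) {
        full <- sum(A[src, tgt, drop = FALSE])
        cc <- if (length(C)) sum(A[C, C, drop = FALSE]) else 0
        full - cc / 2
      } else 0
      s <- length(S); t <- length(T); cc <- length(C)
      L <- s * (t + cc) + cc * (t + (cc - 1) / 2) - m
      d <- s * (t + cc + 2) / 2 + t * (cc + 1) + cc^2 / 2
      c(s, t, cc, m, if (d > 0) L else NA_real_, if (d > 0) L / d else NA_real_)
    })
    res <- do.call(rbind, res)
    out <- tibble(vertex = verts,
                  n_source = as.integer(res[, 1]), n_target = as.integer(res[, 2]),
                  n_reciprocal = as.integer(res[, 3]), m = res[, 4],
                  workload = res[, 5], sv = res[, 6])
  }
  out <- out[ord, ]
  class(out) <- c("sv_tbl", class(out))
  out
}

#' Normalized star-value histogram
#'
#' Bins star values into `bins` equal-width bins on `[0, 1]` (half-open,
#' the last closed at 1) and normalizes counts to sum to one. `NA` star
#' values are dropped and values outside `[0, 1]` are clipped into the end
#' bins; both counts are reported via a message.
#'
#' @param x A numeric vector of star values, an `sv_tbl`, or an `igraph`
#'   network (star values are computed first).
#' @param bins Number of bins (default 20).
#' @param quiet Suppress the dropped/clipped message.
#' @return A tibble of class `sv_dist` with columns `bin`, `lo`, `hi`,
#'   `mid`, `count`, `freq` (`sum(freq) == 1`).
#' @export
sv_distribution <- function(x, bins = 20, quiet = FALSE) {
  if (inherits(x, "igraph")) x <- star_values(x)
  if (is.data.frame(x)) x <- x$sv
  n_na <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("No defined star values to bin.")
  n_clip <- sum(x < 0 | x > 1)
  if (!quiet && (n_na > 0 || n_clip > 0)) {
    inform(sprintf("sv_distribution: %d undefined value(s) dropped, %d value(s) clipped into end bins.",
                   n_na, n_clip))
  }
  x <- pmin(pmax(x, 0), 1)
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble(bin = seq_len(bins), lo = breaks[-(bins + 1)], hi = breaks[-1],
                mid = (breaks[-(bins + 1)] + breaks[-1]) / 2,
                count = counts, freq = counts / sum(counts))
  class(out) <- c("sv_dist", class(out))
  out
}

#' Skewness and excess kurtosis
#'
#' Population moment estimators: skewness is the mean standardized cube,
#' kurtosis the mean standardized fourth power minus 3 (so a normal
#' distribution scores 0 on both).
#'
#' @param values Numeric vector (at least 3 values, nonzero variance), or a
#'   `sv_dist` histogram, in which case bin midpoints weighted by counts are
#'   used.
#' @return A one-row tibble with columns `skewness`, `kurtosis`, `n`.
#' @export
moment_stats <- function(values) {
  if (inherits(values, "sv_dist")) values <- rep(values$mid, values$count)
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("Need at least 3 values for moment statistics.")
  mu <- mean(values)
  s2 <- mean((values - mu)^2)
  if (s2 == 0) abort("Zero variance: skewness and kurtosis are undefined.")
  z <- (values - mu) / sqrt(s2)
  tibble(skewness = mean(z^3), kurtosis = mean(z^4) - 3, n = length(values))
}

#' One-row topological summary of a network
#'
#' Restricts to the largest component (strong for directed, weak for
#' undirected networks by default), then reports vertex count, edge counts
#' under both conventions, diameter, characteristic path length (mean
#' shortest-path length over connected ordered pairs, directed paths on
#' directed networks), mean local clustering coefficient (computed on the
#' undirected view; vertices with fewer than two neighbours are excluded),
#' and mean star value over vertices where it is defined.
#'
#' @param net An `igraph` network.
#' @param mode Component mode; defaults to `"strong"` for directed and
#'   `"weak"` for undirected networks.
#' @param denom Directed star-value denominator convention.
#' @return A one-row tibble: `n_vertices`, `n_edges_unique`, `n_edges_arcs`,
#'   `diameter`, `cpl`, `mean_cc`, `mean_sv`.
#' @examples
#' summarize_network(igraph::make_full_graph(4))
#' @export
summarize_network <- function(net, mode = NULL, denom = "P1") {
  directed <- igraph::is_directed(net)
  mode <- mode %||% if (directed) "strong" else "weak"
  g <- largest_component(net, mode)
  und <- if (directed) igraph::as_undirected(g, mode = "collapse") else g
  cc <- igraph::transitivity(und, type = "local", isolates = "NaN")
  sv <- star_values(g, denom = denom)$sv
  bind_cols(
    tibble(n_vertices = igraph::vcount(g)),
    edge_counts(g),
    tibble(
      diameter = igraph::diameter(g, directed = directed),
      cpl = igraph::mean_distance(g, directed = directed),
      mean_cc = mean(cc[is.finite(cc)]),
      mean_sv = mean(sv, na.rm = TRUE)
    )
  )
}

#' @rdname summarize_network
#' @param x An `igraph` network.
#' @param ... Passed to [summarize_network()].
#' @method glance igraph
#' @export
glance.igraph <- function(x, ...) summarize_network(x, ...)

#' @export
print.nbhd_partition <- function(x, ...) {
  cat(sprintf("<neighbourhood of '%s'>  |S|=%d |T|=%d |C|=%d  m=%.1f\n",
              x$hub, length(x$S), length(x$T), length(x$C), x$m))
  invisible(x)
}
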