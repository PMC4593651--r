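#' Classify a brokered triple into a Gould-Fernandez role
#'
#' For an open directed two-path `s -> b -> t` the broker's role depends
#' only on the three group codes: *coordinator* (all three the same group),
#' *gatekeeper* (source outside the broker's group, broker and target
#' together), *representative* (source and broker together, target
#' outside), *consultant* (source and target together, broker outside) and
#' *liaison* (all three groups distinct). The five cases partition every
#' possible triple. Vectorized over its arguments.
#'
#' @param a_s,a_b,a_t Integer group codes of source, broker and target.
#' @return Character vector of role names.
#' @examples
#' classify_triple(1, 1, 1)   # coordinator
#' classify_triple(2, 1, 1)   # gatekeeper
#' classify_triple(1, 2, 3)   # liaison
#' @export
classify_triple <- function(a_s, a_b, a_t) {
  n <- max(length(a_s), length(a_b), length(a_t))
  a_s <- rep_len(a_s, n); a_b <- rep_len(a_b, n); a_t <- rep_len(a_t, n)
  out <- character(n)
  out[a_s == a_b & a_b == a_t] <- "coordinator"
  out[a_s != a_b & a_b == a_t] <- "gatekeeper"
  out[a_s == a_b & a_t != a_b] <- "representative"
  out[a_s == a_t & a_b != a_s] <- "consultant"
  out[a_s != a_b & a_b != a_t & a_s != a_t] <- "liaison"
  out
}

.role_levels <- c("coordinator", "gatekeeper", "representative", "consultant", "liaison")

# Long table of brokered triples aggregated by (broker, source-group,
# target-group): the common substrate for profiles, top-k lists and the
# best-broker matrices. A triple qualifies when arcs s->b and b->t exist,
# s != t, and the direct arc s->t is absent (t->s does not disqualify).
.brokerage_triples <- function(net, attrs) {
  stopifnot(igraph::is_directed(net))
  codes <- attr_codes(attrs, net)
  verts <- igraph::V(net)$name
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  rows <- vector("list", length(verts))
  for (b in seq_along(verts)) {
    inn <- setdiff(which(A[, b] != 0), b)
    out <- setdiff(which(A[b, ] != 0), b)
    if (length(inn) == 0 || length(out) == 0) next
    grid <- expand.grid(s = inn, t = out, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$s != grid$t, , drop = FALSE]
    if (nrow(grid) == 0) next
    direct <- A[cbind(grid$s, grid$t)] != 0
    grid <- grid[!direct, , drop = FALSE]
    if (nrow(grid) == 0) next
    agg <- stats::aggregate(list(n = rep(1L, nrow(grid))),
                            by = list(code_s = codes[grid$s], code_t = codes[grid$t]),
                            FUN = sum)
    agg$vertex <- verts[b]
    agg$code_b <- codes[b]
    rows[[b]] <- agg
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(vertex = character(), code_b = integer(), code_s = integer(),
                  code_t = integer(), role = character(), n = integer()))
  }
  out <- as_tibble(do.call(rbind, rows))
  out$role <- classify_triple(out$code_s, out$code_b, out$code_t)
  out[, c("vertex", "code_b", "code_s", "code_t", "role", "n")]
}

#' Brokerage profile of a single vertex
#'
#' Unnormalized counts of the five brokerage roles played by `b`: each open
#' directed two-path `s -> b -> t` (arc `s -> t` absent) adds one to the
#' role determined by the three group codes. Every broker of a pair gets
#' full credit regardless of how many other vertices broker the same pair.
#'
#' @param net A directed `igraph` network.
#' @param attrs A [attribute_map()] covering `net`.
#' @param b A vertex name.
#' @return A one-row tibble: `vertex`, the five role counts, `total`.
#' @export
brokerage_profile <- function(net, attrs, b) {
  if (!b %in% igraph::V(net)$name) abort(sprintf("Vertex '%s' is not in the network.", b))
  out <- brokerage_table(net, attrs)
  out[out$vertex == b, ]
}

#' Brokerage profiles for every vertex
#'
#' @inheritParams brokerage_profile
#' @return A tibble of class `brokerage_tbl`: `vertex`, `code`, `label`,
#'   one column per role, and `total` (the number of open directed
#'   two-paths through the vertex).
#' @export
brokerage_table <- function(net, attrs) {
  triples <- .brokerage_triples(net, attrs)
  codes <- attr_codes(attrs, net)
  verts <- igraph::V(net)$name
  base <- tibble(vertex = verts, code = codes, label = attr(attrs, "labels")[codes])
  counts <- triples |>
    group_by(.data$vertex, .data$role) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "n", values_fill = 0L)
  for (r in .role_levels) if (!r %in% names(counts)) counts[[r]] <- 0L
  out <- left_join(base, counts, by = "vertex") |>
    mutate(across(all_of(.role_levels), ~ tidyr::replace_na(.x, 0L))) |>
    mutate(total = rowSums(across(all_of(.role_levels)))) |>
    select("vertex", "code", "label", all_of(.role_levels), "total") |>
    arrange(.data$vertex)
  class(out) <- c("brokerage_tbl", class(out))
  out
}

#' Brokerage census: top brokers and best-broker matrices
#'
#' Produces, from the per-vertex profiles, (i) the top-`k` vertices per role
#' by unnormalized count (ties broken lexicographically) and (ii) one
#' best-broker matrix per role over group pairs. Matrix orientation: rows
#' always index the source's group; columns index the broker/target group
#' for gatekeeper, the target group for representative and liaison (broker
#' from any third group for liaison), and the spokes' own group on the
#' diagonal for coordinator and consultant. Cells with no qualifying triple
#' are `NA`.
#'
#' @inheritParams brokerage_profile
#' @param k Number of top vertices to list per role.
#' @return A list of class `brokerage_census` with elements `profiles`
#'   (a `brokerage_tbl`), `top` (tibble: `role`, `rank`, `vertex`, `count`)
#'   and `best` (named list of K x K character matrices).
#' @export
brokerage_census <- function(net, attrs, k = 10) {
  triples <- .brokerage_triples(net, attrs)
  profiles <- brokerage_table(net, attrs)
  labels <- attr(attrs, "labels")
  K <- length(labels)

  top <- purrr::map_dfr(.role_levels, function(r) {
    ranked <- profiles |>
      select(vertex = "vertex", count = all_of(r)) |>
      filter(.data$count > 0) |>
      arrange(desc(.data$count), .data$vertex) |>
      head(k)
    if (nrow(ranked) == 0) return(tibble(role = character(), rank = integer(),
                                         vertex = character(), count = integer()))
    tibble(role = r, rank = seq_len(nrow(ranked)),
           vertex = ranked$vertex, count = as.integer(ranked$count))
  })

  # role -> (row group, column group) of a triple under the adopted orientation
  cell_of <- function(role, cs, cb, ct) {
    switch(role,
      coordinator    = cbind(cs, ct),   # diagonal: cs == cb == ct
      gatekeeper     = cbind(cs, cb),   # source group x broker(=target) group
      representative = cbind(cs, ct),   # source(=broker) group x target group
      consultant     = cbind(cs, ct),   # diagonal: cs == ct, broker outside
      liaison        = cbind(cs, ct))   # source group x target group
  }
  best <- setNames(lapply(.role_levels, function(r) {
    m <- matrix(NA_character_, K, K, dimnames = list(labels, labels))
    sub <- triples[triples$role == r, , drop = FALSE]
    if (nrow(sub) == 0) return(m)
    cells <- cell_of(r, sub$code_s, sub$code_b, sub$code_t)
    sub$row <- cells[, 1]; sub$col <- cells[, 2]
    agg <- sub |>
      group_by(.data$row, .data$col, .data$vertex) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      group_by(.data$row, .data$col) |>
      arrange(desc(.data$n), .data$vertex, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    m[cbind(agg$row, agg$col)] <- agg$vertex
    m
  }), .role_levels)

  structure(list(profiles = profiles, top = top, best = best),
            orientation = "rows: source group; cols: broker/target group (gatekeeper), target group (representative, liaison), spokes' group diagonal (coordinator, consultant)",
            class = "brokerage_census")
}

#' @export
print.brokerage_census <- function(x, ...) {
  cat("<brokerage census>\n")
  cat("Top brokers per role:\n")
  print(as_tibble(x$top))
  cat("Best-broker matrices for:", paste(names(x$best), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname brokerage_census
#' @param x A `brokerage_census`.
#' @param ... Unused.
#' @method tidy brokerage_census
#' @export
tidy.brokerage_census <- function(x, ...) as_tibble(x$profiles)
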