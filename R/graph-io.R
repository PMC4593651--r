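#' Build a simple network from an edge table
#'
#' Constructs a simple \pkg{igraph} network (no self-loops, no duplicate
#' edges) from a two-column table of endpoints. Vertex identifiers are
#' treated as opaque strings and stored in lexicographic order so that all
#' downstream iteration, and therefore all output tables, are reproducible
#' regardless of input row order.
#'
#' @param edges A data frame whose first two columns are the source and
#'   target vertex of each edge (extra columns are ignored).
#' @param directed Logical; interpret rows as arcs rather than edges.
#' @param quiet Logical; suppress the message reporting dropped self-loops
#'   and collapsed duplicate rows.
#' @return An `igraph` object with character vertex names.
#' @examples
#' net <- network_from_edges(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::ecount(net)
#' @export
network_from_edges <- function(edges, directed = FALSE, quiet = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) abort("`edges` needs at least two columns (source, target).")
  if (nrow(edges) == 0) abort("`edges` is empty: a network needs at least one edge row.")
  src <- as.character(edges[[1]])
  dst <- as.character(edges[[2]])
  loops <- src == dst
  src <- src[!loops]; dst <- dst[!loops]
  if (length(src) == 0) abort("All rows were self-loops; no edges remain.")
  key <- if (directed) paste(src, dst) else paste(pmin(src, dst), pmax(src, dst))
  dup <- duplicated(key)
  if (!quiet && (any(loops) || any(dup))) {
    inform(sprintf("network_from_edges: dropped %d self-loop row(s), collapsed %d duplicate row(s).",
                   sum(loops), sum(dup)))
  }
  verts <- sort(unique(c(src, dst)))
  igraph::graph_from_data_frame(
    data.frame(from = src[!dup], to = dst[!dup], stringsAsFactors = FALSE),
    directed = directed, vertices = verts
  )
}

#' Read a whitespace-delimited edge list
#'
#' Reads a TSV/whitespace-delimited file with one edge per row (first two
#' fields: source, target). Lines starting with `#` and blank lines are
#' skipped. Duplicate rows are collapsed and self-loops dropped, with a
#' message giving the counts.
#'
#' @param path Path to the edge-list file.
#' @inheritParams network_from_edges
#' @return An `igraph` object.
#' @seealso [write_edge_list()], [read_graphml()]
#' @export
read_edge_list <- function(path, directed = FALSE, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(sprintf("'%s' contains no edge rows.", path))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed edge row at line %d of '%s': expected >= 2 columns.",
                  which(keep)[bad[1]], path))
  }
  edges <- data.frame(
    from = vapply(fields, `[[`, character(1), 1),
    to   = vapply(fields, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  network_from_edges(edges, directed = directed, quiet = quiet)
}

#' Write a network as a tab-separated edge list
#'
#' Rows are sorted lexicographically so that writing is deterministic;
#' reading the file back reproduces the identical edge set.
#'
#' @param net An `igraph` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read or write GraphML for interchange
#'
#' Thin wrappers over \pkg{igraph}'s GraphML support; the read side
#' re-normalizes to a simple graph with lexicographically ordered vertices.
#'
#' @param path File path.
#' @param net An `igraph` network.
#' @return `read_graphml()` returns an `igraph`; `write_graphml()` returns
#'   `path` invisibly.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g)
  network_from_edges(as.data.frame(el), directed = igraph::is_directed(g), quiet = TRUE)
}

#' @rdname read_graphml
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Symmetrize a directed network
#'
#' Collapses arcs to undirected edges: the unordered pair \{u, v\} is present
#' iff at least one of the arcs u->v, v->u is. Already-undirected input is
#' returned unchanged with a warning.
#'
#' @param net An `igraph` network.
#' @return An undirected simple `igraph` network.
#' @export
to_undirected <- function(net) {
  if (!igraph::is_directed(net)) {
    warn("to_undirected(): network is already undirected; returning it unchanged.")
    return(net)
  }
  igraph::as_undirected(net, mode = "collapse")
}

#' Extract the largest connected component
#'
#' Returns the induced subnetwork on the largest component. For directed
#' networks the component notion is `"strong"` or `"weak"`; for undirected
#' networks use `"connected"` (synonym: `"weak"`). Size ties are broken by
#' the lexicographically smallest member vertex, so extraction is
#' deterministic.
#'
#' @param net An `igraph` network.
#' @param mode One of `"weak"`, `"strong"`, `"connected"`.
#' @return An `igraph` network.
#' @export
largest_component <- function(net, mode = c("weak", "strong", "connected")) {
  mode <- match.arg(mode)
  if (igraph::vcount(net) == 0) abort("Cannot take the largest component of an empty network.")
  if (mode == "strong" && !igraph::is_directed(net)) {
    abort("mode = 'strong' is only valid on directed networks.")
  }
  if (mode == "connected") mode <- "weak"
  comp <- igraph::components(net, mode = mode)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    first_member <- vapply(cand, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    cand <- cand[order(first_member)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == cand[1]))
}

#' Count edges under both conventions
#'
#' Undirected studies of directed connectomes report edge counts in two
#' conventions: unique unordered pairs, and symmetric arcs (each undirected
#' edge counted once per direction). Both are reported side by side; for a
#' directed network the arc count is the native count.
#'
#' @param net An `igraph` network.
#' @return A one-row tibble with columns `n_edges_unique` and `n_edges_arcs`.
#' @export
edge_counts <- function(net) {
  m <- igraph::ecount(net)
  tibble(
    n_edges_unique = m,
    n_edges_arcs = if (igraph::is_directed(net)) m else 2L * m
  )
}
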