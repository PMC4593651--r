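#' Attach group attributes to a network's vertices
#'
#' Builds a vertex -> group-code table from a (vertex, label) data frame.
#' Labels are mapped to integer codes `1..K` in order of first appearance,
#' unless `label_order` pins an explicit coding (e.g. the eight macaque
#' super-areas in a fixed order). Every vertex of `net` must receive exactly
#' one code; table rows naming vertices absent from `net` are dropped with a
#' warning.
#'
#' @param x A data frame whose first two columns are vertex identifier and
#'   group label.
#' @param net The `igraph` network the attributes belong to.
#' @param label_order Optional character vector of labels fixing the code
#'   assignment (`label_order[1]` -> 1, ...). Must cover every label used.
#' @return A tibble of class `starval_attrs` with columns `vertex`, `label`,
#'   `code`, one row per vertex of `net`, sorted by vertex; the label set in
#'   code order is stored in `attr(, "labels")`.
#' @examples
#' net <- network_from_edges(data.frame(c("a", "b"), c("b", "c")))
#' attribute_map(data.frame(vertex = c("a", "b", "c"),
#'                          label = c("BG", "BG", "TL#2")), net)
#' @export
attribute_map <- function(x, net, label_order = NULL) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) abort("Attribute table needs two columns: vertex, group label.")
  tab <- tibble(vertex = as.character(x[[1]]), label = as.character(x[[2]]))
  tab <- distinct(tab)
  if (anyDuplicated(tab$vertex)) {
    dup <- unique(tab$vertex[duplicated(tab$vertex)])
    abort(paste0("Conflicting group labels for vertex/vertices: ",
                 paste(dup, collapse = ", ")))
  }
  verts <- igraph::V(net)$name
  unknown <- setdiff(tab$vertex, verts)
  if (length(unknown) > 0) {
    warn(paste0("Attribute table names ", length(unknown),
                " vertex/vertices not in the network (ignored): ",
                paste(head(unknown, 10), collapse = ", ")))
    tab <- filter(tab, !.data$vertex %in% unknown)
  }
  missing <- setdiff(verts, tab$vertex)
  if (length(missing) > 0) {
    abort(paste0("No group attribute for vertex/vertices: ",
                 paste(missing, collapse = ", ")))
  }
  labels <- if (is.null(label_order)) unique(tab$label) else label_order
  extra <- setdiff(tab$label, labels)
  if (length(extra) > 0) {
    abort(paste0("`label_order` does not cover label(s): ", paste(extra, collapse = ", ")))
  }
  tab$code <- match(tab$label, labels)
  out <- arrange(tab, .data$vertex)
  attr(out, "labels") <- labels
  class(out) <- c("starval_attrs", class(out))
  out
}

#' Read a vertex-attribute table from TSV
#'
#' Expects two whitespace-delimited columns (vertex, group label); `#`
#' comment lines are skipped. See [attribute_map()] for the coding rules.
#'
#' @param path Path to the attribute TSV.
#' @inheritParams attribute_map
#' @return A `starval_attrs` tibble.
#' @export
read_attribute_table <- function(path, net, label_order = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(sprintf("'%s' contains no attribute rows.", path))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("Malformed attribute row at line %d of '%s'.", which(keep)[bad[1]], path))
  }
  attribute_map(
    data.frame(vertex = vapply(fields, `[[`, character(1), 1),
               label = vapply(fields, `[[`, character(1), 2)),
    net, label_order = label_order
  )
}

#' Number of groups in an attribute map
#' @param attrs A `starval_attrs` tibble.
#' @return Integer `K`.
#' @export
n_groups <- function(attrs) length(attr(attrs, "labels"))

# Integer code vector aligned with V(net)$name; errors if attrs not total.
attr_codes <- function(attrs, net) {
  codes <- attrs$code[match(igraph::V(net)$name, attrs$vertex)]
  if (anyNA(codes)) {
    abort(paste0("Attribute map does not cover vertex/vertices: ",
                 paste(igraph::V(net)$name[is.na(codes)], collapse = ", ")))
  }
  codes
}
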