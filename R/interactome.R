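#' Build an interaction network from an edge table or igraph object
#'
#' The package represents a protein/gene interaction network as an
#' undirected [igraph][igraph::igraph-package] graph with character vertex
#' names (opaque gene identifiers), carrying the S3 class `interactome`.
#' `as_interactome()` normalises an input into that form: duplicate edges
#' are collapsed and self-pairs dropped (unless `keep_self_loops = TRUE`),
#' so downstream degree, clustering and motif computations operate on a
#' simple graph.
#'
#' @param x A two-column data frame / tibble of edge endpoints, an igraph
#'   object, or an existing `interactome`.
#' @param nodes Optional character vector of node identifiers to include
#'   even when isolated (edge lists cannot encode isolated nodes).
#' @param keep_self_loops Keep self-interactions instead of dropping them.
#'   Retained loops count towards degree but are ignored by clustering and
#'   motif computations, which simplify the graph first.
#' @return An `interactome` (an undirected named igraph).
#' @examples
#' net <- as_interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
#' net_nodes(net)
#' @export
as_interactome <- function(x, nodes = NULL, keep_self_loops = FALSE) {
  if (inherits(x, "igraph")) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    edges <- net_edges(structure(g, class = c("interactome", class(g))))
    return(as_interactome(edges, nodes = union(nodes, igraph::V(g)$name),
                          keep_self_loops = keep_self_loops))
  }
  x <- as.data.frame(x)
  if (ncol(x) < 2 && nrow(x) > 0) {
    stop("edge table must have at least two columns", call. = FALSE)
  }
  from <- as.character(x[[1]])
  to <- if (ncol(x) >= 2) as.character(x[[2]]) else character(0)
  loops <- from == to
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- if (keep_self_loops) !duplicated(key) else !loops & !duplicated(key)
  ids <- sort(unique(c(a, b, nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  structure(g, class = c("interactome", class(g)))
}

#' @rdname as_interactome
#' @param net An `interactome` or igraph object.
#' @export
net_nodes <- function(net) {
  igraph::V(net)$name
}

#' @rdname as_interactome
#' @return `net_edges()` returns a tibble with columns `from`, `to`
#'   (endpoints in lexicographic order, rows sorted).
#' @export
net_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) {
    return(tibble::tibble(from = character(0), to = character(0)))
  }
  tibble::tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}

# Simplified copy used by metrics that assume a simple graph.
simple_graph <- function(net) {
  igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Connected components and the giant component
#'
#' `network_components()` partitions the nodes into connected components;
#' `giant_component()` returns the induced sub-network on the largest
#' component (ties broken by the component containing the lexicographically
#' smallest node).
#'
#' @param net An `interactome`.
#' @return `network_components()`: a tibble with columns `id`, `component`
#'   (integer label) ordered so that component 1 is the giant component.
#' @examples
#' net <- as_interactome(data.frame(a = c("a", "c"), b = c("b", "d")))
#' network_components(net)
#' @export
network_components <- function(net) {
  comp <- igraph::components(simple_graph(net))
  ids <- net_nodes(net)
  member <- comp$membership[ids]
  # order components by (size desc, smallest member asc) for determinism
  smallest <- vapply(split(ids, member), min, character(1))
  ord <- order(-comp$csize, smallest)
  relabel <- match(seq_along(comp$csize), ord)
  tibble::tibble(id = ids, component = relabel[member]) |>
    dplyr::arrange(.data$component, .data$id)
}

#' @rdname network_components
#' @export
giant_component <- function(net) {
  parts <- network_components(net)
  keep <- parts$id[parts$component == 1]
  g <- igraph::induced_subgraph(net, keep)
  structure(g, class = c("interactome", class(g)))
}

#' Network density and sub-network density ratio
#'
#' Density is \eqn{2E / (N(N-1))} for a simple undirected graph with
#' \eqn{N \ge 2} nodes.  The density ratio of a disease sub-network to the
#' whole proteome quantifies the tendency of disease proteins to interact
#' among themselves.
#'
#' @param net,sub,whole `interactome` objects.
#' @return A single number. `net_density()` returns 0 for an edgeless graph
#'   and `NA` for graphs with fewer than 2 nodes.
#' @export
net_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) return(NA_real_)
  2 * igraph::ecount(simple_graph(net)) / (n * (n - 1))
}

#' @rdname net_density
#' @export
density_ratio <- function(sub, whole) {
  net_density(sub) / net_density(whole)
}
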