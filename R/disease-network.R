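#' Extract the disease-associated sub-network
#'
#' Builds the sub-network of all interactions with at least one endpoint
#' in the prioritised gene list; first neighbours of prioritised genes are
#' thereby included, so indirect interactions among disease proteins are
#' retained.  Node roles (`"prioritised"` vs `"neighbour"`) are recorded,
#' since the prioritised proteins and the full disease-network protein set
#' are distinct populations in downstream enrichment questions.
#'
#' @param proteome An `interactome` (the full interaction network).
#' @param prioritised Character vector of prioritised gene identifiers;
#'   must intersect the proteome nodes.
#' @return An `interactome` whose nodes are the endpoints of the retained
#'   edges, with a `node_roles` attribute (tibble `id`, `role`).
#' @examples
#' net <- as_interactome(data.frame(a = c("a", "b", "c"),
#'                                  b = c("b", "c", "d")))
#' sub <- extract_disease_network(net, "b")
#' node_roles(sub)
#' @export
extract_disease_network <- function(proteome, prioritised) {
  inside <- intersect(prioritised, net_nodes(proteome))
  if (length(inside) == 0) {
    stop("no prioritised gene is present in the proteome network",
         call. = FALSE)
  }
  edges <- net_edges(proteome)
  keep <- edges$from %in% inside | edges$to %in% inside
  sub_edges <- edges[keep, ]
  # node set = endpoints of the retained edges (an isolated prioritised
  # gene contributes no interactions and so does not appear)
  sub <- as_interactome(sub_edges)
  attr(sub, "node_roles") <- tibble::tibble(
    id = net_nodes(sub),
    role = ifelse(net_nodes(sub) %in% inside, "prioritised", "neighbour")
  )
  sub
}

#' @rdname extract_disease_network
#' @param net A sub-network produced by `extract_disease_network()`.
#' @export
node_roles <- function(net) {
  roles <- attr(net, "node_roles")
  if (is.null(roles)) {
    roles <- tibble::tibble(id = net_nodes(net),
                            role = NA_character_)
  }
  roles
}
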