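#' Breadth-first distance shells around a node
#'
#' @param net An `interactome`.
#' @param node A node identifier.
#' @return A named list mapping each distance `d >= 1` (as character) to
#'   the set of nodes at exactly that shortest-path distance from `node`;
#'   the shells partition the node's connected component (minus itself).
#' @export
distance_shells <- function(net, node) {
  g <- simple_graph(net)
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node,
                                         call. = FALSE)
  d <- igraph::distances(g, v = node)[1, ]
  d <- d[is.finite(d) & d > 0]
  split(names(d), d)
}

#' Class fraction of a distance shell
#'
#' The fraction of the nodes at distance `d` from `node` that belong to
#' the functional class; the focal node itself is never counted.
#'
#' @param net An `interactome`.
#' @param node Focal node identifier.
#' @param class_members Character vector of class members.
#' @param d Distance (>= 1); the shell must be non-empty.
#' @return A number in `[0, 1]`.
#' @export
shell_fraction <- function(net, node, class_members, d) {
  shells <- distance_shells(net, node)
  shell <- shells[[as.character(d)]]
  if (is.null(shell) || length(shell) == 0) {
    stop("empty shell at distance ", d, " from ", node, call. = FALSE)
  }
  shell <- setdiff(shell, node)
  length(intersect(shell, setdiff(class_members, node))) / length(shell)
}

#' Topological segregation of a functional class
#'
#' Measures how much more likely members of a functional class are to lie
#' near other members of the same class than randomly placed proteins
#' would be.  For each class member \eqn{i} and distance \eqn{d}, the
#' shell fraction \eqn{S_i(d)} is the proportion of the nodes at distance
#' \eqn{d} from \eqn{i} that belong to the class; \eqn{\langle S(d)\rangle}
#' averages this over the class members whose shell at \eqn{d} is
#' non-empty.  Each level is normalised by the class frequency among the
#' non-focal nodes, \eqn{(n_j - 1)/(N - 1)} (for a randomly placed class
#' the expected ratio is exactly 1 at every distance; the correction
#' coincides with the classical \eqn{n_j/N} normalisation as \eqn{N}
#' grows), and the scalar segregation index is the average of the ratios
#' over \eqn{d = 1, \dots, d_{max}}:
#' \deqn{S^j = \frac{1}{d_{max}} \sum_{d=1}^{d_{max}}
#'       \frac{\langle S^j(d)\rangle}{(n_j - 1)/(N - 1)}.}
#' \eqn{S^j = 1} for randomly placed classes and \eqn{> 1} for
#' topologically clustered ones.  By default \eqn{d_{max}} is the largest
#' distance at which at least `coverage` of the class members still have
#' a non-empty shell; `mode = "ratio_of_means"` instead divides the
#' average of \eqn{\langle S(d)\rangle} over d by the class frequency.
#'
#' @param net An `interactome`.
#' @param class_members Character vector; at least 2 members must be in
#'   the network.
#' @param d_max Optional maximum distance for the average.
#' @param coverage Fraction of members required to have a non-empty shell
#'   when choosing the default `d_max`.
#' @param mode `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return An object of class `segregation_profile`: list with `profile`
#'   (tibble `d`, `shell_fraction`, `ratio`, `n_members_with_shell`),
#'   `index`, `n_class`, `n_network`, `d_max`.
#' @export
segregation_index <- function(net, class_members, d_max = NULL,
                              coverage = 0.5,
                              mode = c("mean_of_ratios",
                                       "ratio_of_means")) {
  mode <- match.arg(mode)
  g <- simple_graph(net)
  ids <- igraph::V(g)$name
  members <- intersect(class_members, ids)
  n_j <- length(members)
  n <- length(ids)
  if (n_j < 2) {
    stop("class must have at least 2 members in the network",
         call. = FALSE)
  }
  dist <- igraph::distances(g, v = members)
  is_member <- ids %in% members
  dmax_all <- max(dist[is.finite(dist)])
  levels_d <- seq_len(max(1, dmax_all))
  frac <- numeric(0)
  with_shell <- integer(0)
  for (d in levels_d) {
    at_d <- dist == d
    tot <- rowSums(at_d)
    inc <- rowSums(at_d[, is_member, drop = FALSE])
    nonempty <- tot > 0
    with_shell[d] <- sum(nonempty)
    frac[d] <- if (any(nonempty)) mean(inc[nonempty] / tot[nonempty]) else NA
  }
  expected <- (n_j - 1) / (n - 1)
  profile <- tibble::tibble(
    d = levels_d,
    shell_fraction = frac,
    ratio = frac / expected,
    n_members_with_shell = with_shell
  )
  if (is.null(d_max)) {
    eligible <- profile$d[profile$n_members_with_shell >= coverage * n_j]
    d_max <- if (length(eligible) > 0) max(eligible) else 1L
  }
  used <- dplyr::filter(profile, .data$d <= d_max,
                        !is.na(.data$shell_fraction))
  index <- if (mode == "mean_of_ratios") {
    mean(used$ratio)
  } else {
    mean(used$shell_fraction) / expected
  }
  structure(list(profile = profile, index = index, n_class = n_j,
                 n_network = n, d_max = d_max, mode = mode),
            class = "segregation_profile")
}

#' @rdname segregation_index
#' @param genes Character vector — the prioritised list treated as one
#'   class.
#' @export
list_segregation <- function(net, genes, d_max = NULL, coverage = 0.5,
                             mode = c("mean_of_ratios",
                                      "ratio_of_means")) {
  segregation_index(net, genes, d_max = d_max, coverage = coverage,
                    mode = mode)
}

#' @export
print.segregation_profile <- function(x, ...) {
  cat(sprintf(
    "<segregation_profile> S = %.3f over d = 1..%d (class %d of %d nodes)\n",
    x$index, x$d_max, x$n_class, x$n_network))
  invisible(x)
}

#' @method tidy segregation_profile
#' @export
tidy.segregation_profile <- function(x, ...) x$profile

#' @method glance segregation_profile
#' @export
glance.segregation_profile <- function(x, ...) {
  tibble::tibble(index = x$index, n_class = x$n_class,
                 n_network = x$n_network, d_max = x$d_max, mode = x$mode)
}

#' Segregation of every sufficiently large annotated class
#'
#' Runs [segregation_index()] for each functional class with at least
#' `min_size` members in the network (smaller classes are too small for a
#' statistical characterisation and are skipped).
#'
#' @param net An `interactome`.
#' @param annotations Named list mapping class names to gene sets.
#' @param min_size Minimum class size within the network.
#' @inheritParams segregation_index
#' @return A tibble with one row per evaluated class: `class`, `n_class`,
#'   `index`, `d_max`, sorted by descending index.
#' @export
segregate_classes <- function(net, annotations, min_size = 5,
                              coverage = 0.5,
                              mode = c("mean_of_ratios",
                                       "ratio_of_means")) {
  mode <- match.arg(mode)
  ids <- net_nodes(net)
  rows <- purrr::imap(annotations, function(members, cl) {
    inside <- intersect(members, ids)
    if (length(inside) < max(2, min_size)) return(NULL)
    prof <- segregation_index(net, inside, coverage = coverage, mode = mode)
    tibble::tibble(class = cl, n_class = prof$n_class,
                   index = prof$index, d_max = prof$d_max)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$index), .data$class)
}
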