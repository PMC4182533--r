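#' Per-node topological metrics
#'
#' Returns the per-node degree, local clustering coefficient (fraction of
#' a node's neighbour pairs that are connected; `NA` for degree < 2) and
#' topological coefficient.  The topological coefficient of a node
#' \eqn{n} with degree \eqn{k_n \ge 2} is
#' \deqn{TC(n) = \mathrm{mean}_m\, J(n, m) / k_n,}
#' where the mean runs over all nodes \eqn{m \ne n} sharing at least one
#' neighbour with \eqn{n}, and \eqn{J(n,m)} is the number of shared
#' neighbours, plus one if \eqn{n} and \eqn{m} interact directly.  Nodes
#' with fewer than two neighbours have no defined topological coefficient
#' (`NA`).
#'
#' @param net An `interactome`.
#' @return A tibble with columns `id`, `degree`, `clustering`,
#'   `topological_coefficient`.
#' @export
node_metrics <- function(net) {
  g <- simple_graph(net)
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cl[deg < 2] <- NA_real_
  cl[is.nan(cl)] <- NA_real_
  tibble::tibble(
    id = igraph::V(g)$name,
    degree = as.integer(deg),
    clustering = cl,
    topological_coefficient = topological_coefficient(net)
  )
}

#' @rdname node_metrics
#' @param node Optional identifier(s); default all nodes.
#' @return `topological_coefficient()`: a named numeric vector.
#' @export
topological_coefficient <- function(net, node = NULL) {
  g <- simple_graph(net)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  shared <- A %*% A  # shared[i, j] = number of common neighbours
  n <- nrow(A)
  tc <- setNames(rep(NA_real_, n), rownames(A))
  trip <- Matrix::summary(shared)
  # partners of i: j != i with shared[i, j] >= 1
  keep <- trip$i != trip$j & trip$x > 0
  pi_ <- trip$i[keep]
  pj <- trip$j[keep]
  jvals <- trip$x[keep] + A[cbind(pi_, pj)]
  sums <- tapply(jvals, pi_, sum)
  counts <- tapply(jvals, pi_, length)
  idx <- as.integer(names(sums))
  tc[idx] <- (sums / counts) / deg[idx]
  tc[deg < 2] <- NA_real_
  if (!is.null(node)) tc <- tc[node]
  unname_if_scalar(tc)
}

unname_if_scalar <- function(x) if (length(x) == 1) unname(x) else x

#' Mean clustering coefficient by degree
#'
#' Averages the local clustering coefficient over all nodes of each degree
#' \eqn{k \ge 2}.  A decreasing \eqn{C(k)} is the signature of
#' hierarchical modularity in scale-free networks.
#'
#' @param net An `interactome`.
#' @return A tibble with columns `degree`, `mean_clustering`, `n_nodes`.
#' @export
clustering_by_degree <- function(net) {
  node_metrics(net) |>
    dplyr::filter(.data$degree >= 2) |>
    dplyr::group_by(.data$degree) |>
    dplyr::summarise(mean_clustering = mean(.data$clustering),
                     n_nodes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$degree)
}

graph_summary_metrics <- function(g) {
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cl <- cl[deg >= 2 & !is.nan(cl)]
  comp <- igraph::components(g)
  giant_ids <- which(comp$membership == which.max(comp$csize))
  gg <- igraph::induced_subgraph(g, giant_ids)
  c(
    mean_degree = mean(deg),
    mean_clustering = if (length(cl) > 0) mean(cl) else 0,
    mean_shortest_path = igraph::mean_distance(gg, directed = FALSE),
    diameter = igraph::diameter(gg, directed = FALSE),
    density = igraph::edge_density(g),
    n_components = comp$no
  )
}

#' Compare a network against an Erdős–Rényi ensemble
#'
#' Generates `n_random` Erdős–Rényi graphs \eqn{G(N, M)} with the same
#' number of nodes and edges as the input (uniform edge sampling without
#' replacement) and reports, for each global metric, the observed value,
#' the ensemble mean and standard deviation, the z-score
#' \eqn{(x - \mu)/\sigma} and a two-sided normal p-value.  Mean shortest
#' path and diameter are computed within the giant component.
#'
#' @param net An `interactome`.
#' @param n_random Ensemble size.
#' @param seed Integer seed for the ensemble.
#' @return An object of class `topology_report`: list with `comparison`
#'   (tibble `metric`, `observed`, `null_mean`, `null_sd`, `z`, `p_value`),
#'   `per_node` (from [node_metrics()]), `n_random` and `seed`.
#' @export
er_ensemble_compare <- function(net, n_random = 100, seed = 1L) {
  g <- simple_graph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  observed <- graph_summary_metrics(g)
  set.seed(seed)
  draws <- vapply(seq_len(n_random),
                  function(i) graph_summary_metrics(igraph::sample_gnm(n, m)),
                  numeric(length(observed)))
  mu <- rowMeans(draws)
  sdv <- apply(draws, 1, sd)
  z <- ifelse(sdv > 0, (observed - mu) / sdv, NA_real_)
  comparison <- tibble::tibble(
    metric = names(observed),
    observed = unname(observed),
    null_mean = unname(mu),
    null_sd = unname(sdv),
    z = unname(z),
    p_value = unname(2 * pnorm(-abs(z)))
  )
  structure(list(comparison = comparison, per_node = node_metrics(net),
                 n_random = n_random, seed = seed),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> vs %d Erdős-Rényi draws (seed %d)\n",
              x$n_random, x$seed))
  print(x$comparison)
  invisible(x)
}

#' @method tidy topology_report
#' @export
tidy.topology_report <- function(x, ...) x$comparison

#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$per_node),
    n_random = x$n_random,
    seed = x$seed,
    n_significant = sum(x$comparison$p_value < 0.05, na.rm = TRUE)
  )
}
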