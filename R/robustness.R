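#' Failure-attack tolerance by sequential node removal
#'
#' Removes nodes in batches of `ceiling(step_fraction * N)` in a
#' prescribed order and records, after every batch, the fraction of nodes
#' removed, the number of surviving interactions, and the cumulative
#' number of secondary extinctions — nodes not deliberately removed whose
#' degree has fallen to zero.  Strategies:
#'
#' * `"random"`: a seeded uniform removal order (failure).
#' * `"degree_desc"`: highest to lowest degree (attack on hubs).
#' * `"degree_asc"`: lowest to highest degree.
#' * `"gene_set"`: removal restricted to a supplied gene set (e.g. the
#'   genes of SNP locus windows), in seeded random order within the set.
#'
#' Degree orderings use the degrees of the original network (static
#' ordering, ties broken lexicographically); set `recalculate = TRUE` to
#' re-rank the survivors by current degree before every batch.
#'
#' @param net An `interactome`.
#' @param strategy Removal strategy (see above).
#' @param step_fraction Batch size as a fraction of the node count, in
#'   `(0, 1]`.
#' @param seed Integer seed (used by `"random"` and `"gene_set"`).
#' @param gene_set Character vector, required for `strategy = "gene_set"`.
#' @param recalculate Recompute the degree ordering on the surviving
#'   graph before each batch (degree strategies only).
#' @return A tibble of class `removal_trajectory` with columns `step`,
#'   `fraction_removed`, `n_removed`, `surviving_edges`,
#'   `secondary_extinctions` (cumulative); attributes `strategy`, `seed`.
#'   Step 0 records the intact network.
#' @examples
#' star <- as_interactome(data.frame(from = "hub", to = paste0("l", 1:5)))
#' removal_trajectory(star, "degree_desc", step_fraction = 1 / 6)
#' @export
removal_trajectory <- function(net,
                               strategy = c("random", "degree_desc",
                                            "degree_asc", "gene_set"),
                               step_fraction = 0.05, seed = 1L,
                               gene_set = NULL, recalculate = FALSE) {
  strategy <- match.arg(strategy)
  if (step_fraction <= 0 || step_fraction > 1) {
    stop("step_fraction must be in (0, 1]", call. = FALSE)
  }
  g <- simple_graph(net)
  ids <- igraph::V(g)$name
  n <- length(ids)
  deg0 <- setNames(as.integer(igraph::degree(g)), ids)
  adj <- lapply(igraph::as_adj_list(g), igraph::as_ids)
  names(adj) <- ids
  order_ids <- switch(strategy,
    random = { set.seed(seed); sample(ids) },
    degree_desc = ids[order(-deg0, ids)],
    degree_asc = ids[order(deg0, ids)],
    gene_set = {
      if (is.null(gene_set)) {
        stop("strategy 'gene_set' requires gene_set", call. = FALSE)
      }
      inset <- intersect(gene_set, ids)
      set.seed(seed)
      sample(inset)
    }
  )
  batch <- max(1L, ceiling(step_fraction * n))
  alive <- setNames(rep(TRUE, n), ids)
  deg <- deg0
  removed_set <- setNames(rep(FALSE, n), ids)
  edges_alive <- igraph::ecount(g)
  extinct <- 0L
  counted <- setNames(rep(FALSE, n), ids)
  steps <- list(tibble::tibble(step = 0L, fraction_removed = 0,
                               n_removed = 0L,
                               surviving_edges = edges_alive,
                               secondary_extinctions = 0L))
  remaining <- order_ids
  step <- 0L
  n_removed <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    if (recalculate && strategy %in% c("degree_desc", "degree_asc")) {
      remaining <- if (strategy == "degree_desc") {
        remaining[order(-deg[remaining], remaining)]
      } else {
        remaining[order(deg[remaining], remaining)]
      }
    }
    this <- head(remaining, batch)
    remaining <- setdiff(remaining, this)
    for (v in this) {
      if (!alive[v]) { removed_set[v] <- TRUE; next }
      removed_set[v] <- TRUE
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      edges_alive <- edges_alive - length(nb)
      alive[v] <- FALSE
      for (u in nb) {
        deg[u] <- deg[u] - 1L
        if (deg[u] == 0L && !removed_set[u] && !counted[u] && deg0[u] > 0L) {
          extinct <- extinct + 1L
          counted[u] <- TRUE
        }
      }
      deg[v] <- 0L
    }
    n_removed <- n_removed + length(this)
    steps[[step + 1L]] <- tibble::tibble(
      step = step,
      fraction_removed = n_removed / n,
      n_removed = n_removed,
      surviving_edges = edges_alive,
      secondary_extinctions = extinct
    )
  }
  out <- dplyr::bind_rows(steps)
  structure(out, class = c("removal_trajectory", class(out)),
            strategy = strategy, seed = seed)
}

#' Average random-failure trajectories over seeds
#'
#' @param net An `interactome`.
#' @param step_fraction Batch size fraction, as in [removal_trajectory()].
#' @param seeds Integer vector of seeds to average over.
#' @return A tibble with the per-step mean `surviving_edges` and
#'   `secondary_extinctions` across seeds.
#' @export
mean_random_trajectory <- function(net, step_fraction = 0.05,
                                   seeds = 1:10) {
  purrr::map_dfr(seeds, function(s) {
    tr <- removal_trajectory(net, "random", step_fraction, seed = s)
    dplyr::mutate(tibble::as_tibble(tr), seed = s)
  }) |>
    dplyr::group_by(.data$step, .data$fraction_removed) |>
    dplyr::summarise(
      surviving_edges = mean(.data$surviving_edges),
      secondary_extinctions = mean(.data$secondary_extinctions),
      .groups = "drop"
    )
}
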