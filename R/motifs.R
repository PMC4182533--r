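#' Canonical decimal identifier of a small undirected subgraph
#'
#' Encodes an undirected k-node graph as a bidirectional (symmetric,
#' zero-diagonal) k-by-k adjacency matrix and takes the minimum, over all
#' k! node permutations, of the row-major bit string read as a binary
#' integer.  This is the decimal subgraph-id convention of classic motif
#' software: the 3-path is id 78, the triangle id 238 and the 4-clique
#' id 31710.
#'
#' @param adjacency A square symmetric 0/1 matrix (k in 2..4).
#' @return An integer id.
#' @examples
#' path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
#' canonical_subgraph_id(path3)  # 78
#' @export
canonical_subgraph_id <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- nrow(a)
  stopifnot(k == ncol(a), k >= 2, k <= 4)
  a <- (a != 0) * 1L
  diag(a) <- 0L
  perms <- permutations_of(k)
  best <- Inf
  weights <- 2^((k * k - 1):0)
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    v <- as.vector(t(a[p, p, drop = FALSE]))
    val <- sum(v * weights)
    if (val < best) best <- val
  }
  as.integer(best)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# canonical id per igraph isomorphism class, connected classes only
motif_class_map <- function(k) {
  key <- as.character(k)
  if (!is.null(.motif_cache[[key]])) return(.motif_cache[[key]])
  n_classes <- if (k == 3) 4L else 11L
  ids <- rep(NA_integer_, n_classes)
  for (i in seq_len(n_classes)) {
    g <- igraph::graph_from_isomorphism_class(k, i - 1L, directed = FALSE)
    if (igraph::is_connected(g)) {
      ids[i] <- canonical_subgraph_id(
        igraph::as_adjacency_matrix(g, sparse = FALSE))
    }
  }
  .motif_cache[[key]] <- ids
  ids
}

.motif_cache <- new.env(parent = emptyenv())

#' Census of connected induced k-node subgraphs
#'
#' Counts every connected induced subgraph on `k` nodes (k = 3 or 4)
#' exactly once, keyed by its canonical decimal id
#' ([canonical_subgraph_id()]).
#'
#' @param net An `interactome`.
#' @param k Subgraph size, 3 or 4.
#' @return A tibble with columns `id` (canonical id, ascending), `count`.
#'   Classes that do not occur are reported with count 0, so the counts
#'   always sum to the total number of connected induced k-subgraphs.
#' @export
subgraph_census <- function(net, k) {
  if (!k %in% c(3L, 4L)) stop("k must be 3 or 4", call. = FALSE)
  g <- simple_graph(net)
  counts <- suppressWarnings(igraph::motifs(g, size = k))
  ids <- motif_class_map(k)
  keep <- !is.na(ids)
  tibble::tibble(id = ids[keep], count = as.numeric(counts[keep])) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$id)
}

#' Degree-preserving randomisation by edge switching
#'
#' Randomises a network by repeated double-edge swaps
#' (a–b, c–d becomes a–d, c–b), rejecting swaps that would create
#' self-loops or duplicate edges, so the degree of every node is exactly
#' preserved.  This is the standard null model for motif detection.
#'
#' @param net An `interactome`.
#' @param swaps_per_edge Number of swap trials per edge.
#' @param seed Integer seed.
#' @return A randomised `interactome` with the same degree sequence.
#' @export
switch_randomize <- function(net, swaps_per_edge = 10, seed = 1L) {
  g <- simple_graph(net)
  set.seed(seed)
  r <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = max(1, swaps_per_edge * igraph::ecount(g))))
  as_interactome(r)
}

#' Motif and anti-motif detection against the switching null
#'
#' Computes the connected k-subgraph census of the network and of
#' `n_random` degree-preserving randomisations, and reports per subgraph
#' class the real count, null mean and standard deviation, the z-score
#' \eqn{(real - \mu)/\sigma}, and the call: `"motif"` when
#' \eqn{z \ge} `z_threshold`, `"anti-motif"` when \eqn{z \le -}
#' `z_threshold`, otherwise `"neutral"`.  Classes with zero null variance
#' and a real count equal to the null mean are `"neutral"` (z undefined).
#'
#' @param net An `interactome`.
#' @param k Subgraph size, 3 or 4.
#' @param n_random Number of randomised networks.
#' @param z_threshold Absolute z-score for a motif/anti-motif call.
#' @param swaps_per_edge Swap trials per edge for each randomisation.
#' @param seed Integer seed; draw `i` uses `seed + i`.
#' @return A tibble of class `motif_census` with columns `id`,
#'   `real_count`, `null_mean`, `null_sd`, `z`, `call`; attributes `k`,
#'   `n_random`, `z_threshold`, `seed`.
#' @export
motif_zscores <- function(net, k, n_random = 100, z_threshold = 2,
                          swaps_per_edge = 10, seed = 1L) {
  real <- subgraph_census(net, k)
  null_counts <- vapply(seq_len(n_random), function(i) {
    subgraph_census(switch_randomize(net, swaps_per_edge, seed + i), k)$count
  }, numeric(nrow(real)))
  if (nrow(real) == 1) null_counts <- matrix(null_counts, nrow = 1)
  mu <- rowMeans(null_counts)
  sdv <- apply(null_counts, 1, sd)
  z <- ifelse(sdv > 0, (real$count - mu) / sdv, NA_real_)
  call <- dplyr::case_when(
    !is.na(z) & z >= z_threshold ~ "motif",
    !is.na(z) & z <= -z_threshold ~ "anti-motif",
    is.na(z) & real$count != mu ~ "divergent",
    .default = "neutral"
  )
  out <- tibble::tibble(id = real$id, real_count = real$count,
                        null_mean = mu, null_sd = sdv, z = z, call = call)
  structure(out, class = c("motif_census", class(out)),
            k = k, n_random = n_random, z_threshold = z_threshold,
            seed = seed)
}

#' Per-protein motif participation
#'
#' Enumerates every connected induced k-subgraph of the network and, for
#' each queried gene, counts the instances whose subgraph class was called
#' a motif in the supplied census (`classes = "motif"`; use
#' `classes = "all"` to count instances of every class).  Ranks the genes
#' by participation, ties broken lexicographically — the route by which
#' the most motif-associated disease proteins are identified.
#'
#' @param net An `interactome`.
#' @param census A `motif_census` from [motif_zscores()].
#' @param genes Character vector of genes to tabulate.
#' @param classes Count only `"motif"`-called classes (default) or
#'   `"all"` classes.
#' @return A tibble with columns `id`, `participation`, sorted by
#'   descending participation.
#' @export
motif_participation <- function(net, census, genes,
                                classes = c("motif", "all")) {
  classes <- match.arg(classes)
  k <- attr(census, "k")
  wanted <- if (classes == "motif") {
    census$id[census$call == "motif"]
  } else {
    census$id
  }
  counts <- setNames(rep(0L, length(genes)), sort(genes))
  if (length(wanted) > 0) {
    inst <- enumerate_connected_subgraphs(net, k)
    if (nrow(inst$sets) > 0) {
      hit <- inst$ids %in% wanted
      sets <- inst$sets[hit, , drop = FALSE]
      if (nrow(sets) > 0) {
        tab <- table(factor(as.vector(sets), levels = names(counts)))
        counts <- counts + as.integer(tab)
      }
    }
  }
  tibble::tibble(id = names(counts), participation = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$participation), .data$id)
}

# ESU-style exhaustive enumeration of connected induced k-subgraphs.
# Returns the node sets (character matrix, one row per instance) and the
# canonical id of each instance.
enumerate_connected_subgraphs <- function(net, k) {
  g <- simple_graph(net)
  ids <- igraph::V(g)$name
  n <- length(ids)
  adj <- lapply(igraph::as_adj_list(g), function(vs) as.integer(vs))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  out_sets <- list()
  extend <- function(sub, ext, v) {
    if (length(sub) == k) {
      out_sets[[length(out_sets) + 1L]] <<- sub
      return(invisible())
    }
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      new_ext <- union(ext, setdiff(adj[[w]][adj[[w]] > v],
                                    unlist(lapply(sub, function(s) adj[[s]]))))
      extend(c(sub, w), new_ext, v)
    }
  }
  for (v in seq_len(n)) {
    extend(v, adj[[v]][adj[[v]] > v], v)
  }
  if (length(out_sets) == 0) {
    return(list(sets = matrix(character(0), 0, k), ids = integer(0)))
  }
  sets <- do.call(rbind, out_sets)
  inst_ids <- vapply(seq_len(nrow(sets)), function(i) {
    canonical_subgraph_id(as.matrix(A[sets[i, ], sets[i, ]]))
  }, integer(1))
  list(sets = matrix(ids[sets], ncol = k), ids = inst_ids)
}

#' @method tidy motif_census
#' @export
tidy.motif_census <- function(x, ...) tibble::as_tibble(x)

#' @method glance motif_census
#' @export
glance.motif_census <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"),
    n_random = attr(x, "n_random"),
    z_threshold = attr(x, "z_threshold"),
    n_motifs = sum(x$call == "motif"),
    n_anti_motifs = sum(x$call == "anti-motif"),
    total_subgraphs = sum(x$real_count)
  )
}
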