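#' Random walk with restart over an interaction network
#'
#' Diffusion-based gene prioritisation: walkers are released from the
#' training set of known disease genes and diffuse along the interaction
#' network, so that genes better connected to the training set accumulate
#' more stationary probability.  The iteration is
#' \deqn{p^{(t+1)} = (1 - r)\,W p^{(t)} + r\,e,}
#' where \eqn{W} is the column-normalised adjacency matrix (the walker
#' leaves a node along each incident edge with equal probability), \eqn{e}
#' is uniform over the training genes present in the network, and \eqn{r}
#' is the restart probability.  Iteration starts at \eqn{p^{(0)} = e} and
#' stops when the L1 difference between successive vectors falls below
#' `tol` or after `max_iter` iterations.  Probability mass is conserved
#' exactly: isolated nodes retain their mass between restarts (a
#' self-retaining column), so the vector sums to 1 at every iteration.
#'
#' @param net An `interactome`.
#' @param training Character vector of training gene identifiers; at least
#'   one must be present in the network.
#' @param r Restart probability in `(0, 1]`.  With `r = 1` the result is
#'   the restart vector itself.
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `rwr_result`: a list with `probabilities`
#'   (tibble `id`, `prob` in node order), `r`, `tol`, `iterations`,
#'   `converged` and `training_in_network`.
#' @examples
#' net <- as_interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
#' res <- rwr(net, training = "a", r = 0.5)
#' tidy(res)
#' @seealso [rwr_exact()] for the direct linear solve of the same
#'   stationary state, [select_by_steady_state()] for turning the
#'   probabilities into a gene selection.
#' @export
rwr <- function(net, training, r = 0.5, tol = 1e-10, max_iter = 10000L) {
  W <- walk_matrix(net)
  e <- restart_vector(net, training)
  if (r <= 0 || r > 1) stop("restart r must be in (0, 1]", call. = FALSE)
  p <- e
  iterations <- 0L
  converged <- FALSE
  if (r == 1) {
    converged <- TRUE
  } else {
    for (i in seq_len(max_iter)) {
      p_new <- as.numeric((1 - r) * (W %*% p)) + r * e
      iterations <- i
      if (sum(abs(p_new - p)) < tol) {
        p <- p_new
        converged <- TRUE
        break
      }
      p <- p_new
    }
  }
  new_rwr_result(net, p, e, r, tol, iterations, converged)
}

#' Exact stationary state of the random walk with restart
#'
#' Solves the stationary equation \eqn{(I - (1-r) W) p = r e} directly.
#' Intended as the reference solution for moderate networks and as an
#' independent check of the iterative solver in [rwr()].
#'
#' @inheritParams rwr
#' @return An `rwr_result` with `iterations = 0` and `converged = TRUE`.
#' @export
rwr_exact <- function(net, training, r = 0.5) {
  if (r <= 0 || r > 1) stop("restart r must be in (0, 1]", call. = FALSE)
  W <- walk_matrix(net)
  e <- restart_vector(net, training)
  n <- length(e)
  A <- Matrix::Diagonal(n) - (1 - r) * W
  p <- as.numeric(Matrix::solve(A, r * e))
  new_rwr_result(net, p, e, r, tol = 0, iterations = 0L, converged = TRUE)
}

walk_matrix <- function(net) {
  g <- simple_graph(net)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = scale)
  dangling <- which(deg == 0)
  if (length(dangling) > 0) {
    # isolated nodes retain their own mass so |p|_1 stays 1
    W <- W + Matrix::sparseMatrix(i = dangling, j = dangling,
                                  x = 1, dims = dim(A))
  }
  dimnames(W) <- dimnames(A)
  W
}

restart_vector <- function(net, training) {
  ids <- net_nodes(net)
  inside <- intersect(training, ids)
  if (length(inside) == 0) {
    stop("no training gene is present in the network", call. = FALSE)
  }
  e <- setNames(numeric(length(ids)), ids)
  e[inside] <- 1 / length(inside)
  e
}

new_rwr_result <- function(net, p, e, r, tol, iterations, converged) {
  structure(list(
    probabilities = tibble::tibble(id = net_nodes(net), prob = unname(p)),
    r = r, tol = tol, iterations = iterations, converged = converged,
    training_in_network = names(e)[e > 0]
  ), class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf(
    "<rwr_result> %d nodes, r = %g, %d iterations, converged: %s\n",
    nrow(x$probabilities), x$r, x$iterations, x$converged))
  invisible(x)
}

#' @method tidy rwr_result
#' @export
tidy.rwr_result <- function(x, ...) {
  dplyr::arrange(x$probabilities, dplyr::desc(.data$prob), .data$id)
}

#' @method glance rwr_result
#' @export
glance.rwr_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$probabilities),
    n_training = length(x$training_in_network),
    r = x$r, tol = x$tol, iterations = x$iterations,
    converged = x$converged,
    total_probability = sum(x$probabilities$prob)
  )
}

#' Select genes from the steady-state probabilities
#'
#' Ranks the candidate genes by their stationary probability (descending,
#' ties broken lexicographically) and selects either the top `value` genes
#' (`rule = "top_k"`) or all candidates with probability strictly above
#' `value` (`rule = "prob_threshold"`).
#'
#' @param p An `rwr_result`.
#' @param candidates Character vector of candidate genes.
#' @param rule `"top_k"` or `"prob_threshold"`.
#' @param value The `k` or the probability threshold.
#' @return A character vector of selected genes (sorted).
#' @export
select_by_steady_state <- function(p, candidates,
                                   rule = c("top_k", "prob_threshold"),
                                   value) {
  rule <- match.arg(rule)
  probs <- p$probabilities
  cand <- probs[probs$id %in% candidates, ]
  cand <- dplyr::arrange(cand, dplyr::desc(.data$prob), .data$id)
  if (rule == "top_k") {
    k <- as.integer(value)
    if (k < 0) stop("k must be non-negative", call. = FALSE)
    if (k > nrow(cand)) {
      warning("k exceeds the number of candidates; returning all",
              call. = FALSE)
      k <- nrow(cand)
    }
    sort(cand$id[seq_len(k)])
  } else {
    sort(cand$id[cand$prob > value])
  }
}

#' Select genes from an external ranked list by p-value
#'
#' Returns all identifiers with p-value strictly below the threshold,
#' mirroring the selection applied to an external relatedness ranking
#' (e.g. a text-mining prioritisation reporting per-gene p-values).
#'
#' @param ranked A ranked-list tibble `(id, score, p_value)`.
#' @param p_threshold Strict upper bound on the p-value.
#' @return A character vector of selected genes (sorted).
#' @export
select_external <- function(ranked, p_threshold = 0.1) {
  sort(ranked$id[ranked$p_value < p_threshold])
}

#' Consensus of the two prioritisation routes
#'
#' Combines the diffusion-based selection and the external-ranking
#' selection into the final prioritised list.  The default combiner is
#' the intersection of the two selections united with the training set
#' (the weakest reading of a consensus "together with the training set");
#' `mode = "union"` unites all three.  If `nodes` is supplied the result
#' is restricted to genes present in the network.
#'
#' @param rwr_selected,external_selected,training Character vectors.
#' @param mode `"intersection"` (default) or `"union"`.
#' @param nodes Optional character vector of network nodes to restrict to.
#' @return An object of class `prioritisation_result` with fields
#'   `consensus`, `rwr_selected`, `external_selected`, `training`, `mode`.
#' @export
consensus <- function(rwr_selected, external_selected, training,
                      mode = c("intersection", "union"), nodes = NULL) {
  mode <- match.arg(mode)
  core <- if (mode == "intersection") {
    intersect(rwr_selected, external_selected)
  } else {
    union(rwr_selected, external_selected)
  }
  out <- sort(union(core, training))
  if (!is.null(nodes)) out <- intersect(out, nodes)
  structure(list(
    consensus = out,
    rwr_selected = sort(rwr_selected),
    external_selected = sort(external_selected),
    training = sort(training),
    mode = mode
  ), class = "prioritisation_result")
}

#' @export
print.prioritisation_result <- function(x, ...) {
  cat(sprintf(
    "<prioritisation_result> %d consensus genes (%s of %d diffusion-selected and %d externally selected, plus %d training)\n",
    length(x$consensus), x$mode, length(x$rwr_selected),
    length(x$external_selected), length(x$training)))
  invisible(x)
}

#' @method tidy prioritisation_result
#' @export
tidy.prioritisation_result <- function(x, ...) {
  tibble::tibble(
    id = x$consensus,
    in_rwr = x$consensus %in% x$rwr_selected,
    in_external = x$consensus %in% x$external_selected,
    in_training = x$consensus %in% x$training
  )
}

#' @method glance prioritisation_result
#' @export
glance.prioritisation_result <- function(x, ...) {
  tibble::tibble(
    n_consensus = length(x$consensus),
    n_rwr = length(x$rwr_selected),
    n_external = length(x$external_selected),
    n_training = length(x$training),
    mode = x$mode
  )
}
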