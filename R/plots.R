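#' @method autoplot removal_trajectory
#' @export
autoplot.removal_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("surviving_edges", "secondary_extinctions"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction_removed, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(
      x = "fraction of nodes removed", y = NULL,
      title = sprintf("Node removal (%s)", attr(object, "strategy"))
    )
}

#' Compare removal strategies on one panel
#'
#' @param net An `interactome`.
#' @param strategies Character vector of strategies to draw.
#' @param step_fraction,seed Passed to [removal_trajectory()].
#' @return A ggplot of surviving interactions against fraction removed.
#' @export
plot_attack_tolerance <- function(net,
                                  strategies = c("random", "degree_desc",
                                                 "degree_asc"),
                                  step_fraction = 0.05, seed = 1L) {
  curves <- purrr::map_dfr(strategies, function(s) {
    tr <- removal_trajectory(net, s, step_fraction, seed = seed)
    dplyr::mutate(tibble::as_tibble(tr), strategy = s)
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fraction_removed,
                                       .data$surviving_edges,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "surviving interactions", colour = "strategy")
}

#' @method autoplot motif_census
#' @export
autoplot.motif_census <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$id <- factor(df$id)
  ggplot2::ggplot(df, ggplot2::aes(.data$id, .data$z, fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * attr(object, "z_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("%d-node subgraph id", attr(object, "k")),
                  y = "z-score", fill = NULL)
}

#' @method autoplot segregation_profile
#' @export
autoplot.segregation_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$d, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance d",
                  y = "shell ratio  ⟨S(d)⟩ / class frequency",
                  title = sprintf("Segregation index S = %.2f",
                                  object$index))
}

#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object, ...) {
  df <- dplyr::filter(object$comparison, !is.na(.data$z))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$z)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("z-score vs %d Erdős-Rényi draws",
                              object$n_random))
}
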