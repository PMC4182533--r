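#' Identify hub proteins
#'
#' Hubs are the nodes whose degree is strictly greater than the mean
#' degree of the network.
#'
#' @param net An `interactome`.
#' @return A sorted character vector of hub identifiers.
#' @export
identify_hubs <- function(net) {
  g <- simple_graph(net)
  deg <- igraph::degree(g)
  sort(names(deg)[deg > mean(deg)])
}

new_enrichment_result <- function(test, counts, p, adjusted_p = p,
                                  method = "none", direction) {
  structure(tibble::tibble(
    test = test,
    !!!counts,
    p_value = p,
    adjusted_p = adjusted_p,
    adjustment = method,
    direction = direction
  ), class = c("enrichment_result", class(tibble::tibble())))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability \eqn{P(X \ge x)} that a sample of
#' `sample_size` drawn without replacement from a population of
#' `pop_size` containing `pop_successes` marked elements contains at
#' least `sample_successes` of them.  Used, e.g., to ask whether proteome
#' hubs are over-represented among the prioritised proteins.
#'
#' @param pop_size,pop_successes,sample_size,sample_successes Counts.
#' @return An `enrichment_result` tibble row.
#' @examples
#' hypergeom_overrep(10, 4, 5, 4)$p_value  # 6/252
#' @export
hypergeom_overrep <- function(pop_size, pop_successes, sample_size,
                              sample_successes) {
  if (sample_successes > min(sample_size, pop_successes) ||
      pop_successes > pop_size || sample_size > pop_size) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  p <- phyper(sample_successes - 1, pop_successes,
              pop_size - pop_successes, sample_size, lower.tail = FALSE)
  expected <- sample_size * pop_successes / pop_size
  new_enrichment_result(
    "hypergeometric",
    list(pop_size = pop_size, pop_successes = pop_successes,
         sample_size = sample_size, sample_successes = sample_successes),
    p = p,
    direction = if (sample_successes >= expected) "over" else "under"
  )
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact test of association in a 2x2 table with fixed marginals.  The
#' two-sided p-value sums the probabilities of all tables no more
#' probable than the observed one (the conventional exact definition);
#' `alternative = "greater"`/`"less"` give the one-sided tails on the
#' `[1, 1]` cell.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An `enrichment_result` tibble row.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value  # 2/252
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  ft <- fisher.test(table, alternative = alternative)
  expected <- sum(table[1, ]) * sum(table[, 1]) / sum(table)
  new_enrichment_result(
    "fisher_exact",
    list(a = table[1, 1], b = table[1, 2], c = table[2, 1],
         d = table[2, 2]),
    p = ft$p.value,
    direction = if (table[1, 1] >= expected) "over" else "under"
  )
}

#' Enrichment of differentially expressed genes in a prioritised list
#'
#' Partitions the measured universe by prioritisation status and by
#' differential expression (adjusted p below `alpha`) and tests the 2x2
#' table with Fisher's exact test — the check that a prioritised disease
#' list is supported by expression changes in patient tissue.
#'
#' @param prioritised Character vector of prioritised genes.
#' @param de A DE tibble `(id, p_adj)`.
#' @param universe Character vector of measured genes; defaults to the DE
#'   table's genes.
#' @param alpha Adjusted-p threshold for calling a gene DE.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return An `enrichment_result` tibble row with the full 2x2 counts.
#' @export
de_enrichment <- function(prioritised, de, universe = de$id,
                          alpha = 0.05, alternative = "two.sided") {
  universe <- unique(universe)
  de_genes <- de$id[de$p_adj < alpha]
  in_pri <- universe %in% prioritised
  in_de <- universe %in% de_genes
  tab <- matrix(c(sum(in_pri & in_de), sum(in_pri & !in_de),
                  sum(!in_pri & in_de), sum(!in_pri & !in_de)),
                nrow = 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab, alternative = alternative)
  res$test <- "de_enrichment"
  res
}

#' Hub connectivity of a single protein
#'
#' Tests whether the first neighbours of a protein are enriched in
#' proteome hubs: a 2x2 Fisher test of neighbour status against hub
#' status over the proteome nodes, with the focal protein excluded.
#' Neighbours are taken from `net` (typically the disease sub-network);
#' hub status and the population come from the proteome.
#'
#' @param net An `interactome` supplying the neighbourhood.
#' @param protein Focal protein identifier; must have at least one
#'   neighbour in `net`.
#' @param hubs Character vector of hub identifiers
#'   (see [identify_hubs()]), measured on the proteome.
#' @param proteome The full `interactome` (the population).
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return An `enrichment_result` tibble row.
#' @export
hub_neighbour_test <- function(net, protein, hubs, proteome,
                               alternative = "two.sided") {
  if (!protein %in% net_nodes(net)) {
    stop("protein not in network: ", protein, call. = FALSE)
  }
  nb <- igraph::as_ids(igraph::neighbors(simple_graph(net), protein))
  nb <- setdiff(nb, protein)
  if (length(nb) == 0) {
    stop("protein has no neighbours: ", protein, call. = FALSE)
  }
  pop <- setdiff(net_nodes(proteome), protein)
  is_nb <- pop %in% nb
  is_hub <- pop %in% hubs
  tab <- matrix(c(sum(is_nb & is_hub), sum(is_nb & !is_hub),
                  sum(!is_nb & is_hub), sum(!is_nb & !is_hub)),
                nrow = 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab, alternative = alternative)
  res$test <- "hub_neighbour"
  res <- dplyr::mutate(res, protein = protein, .after = "test")
  res
}

#' Functional-category over-representation (binomial test, Bonferroni)
#'
#' For every annotated class with at least `min_size` genes in the
#' reference list, tests whether the gene list contains more class
#' members than expected under a binomial model with success probability
#' equal to the class's frequency in the annotated reference (the
#' reference genes carrying at least one annotation — the classified
#' universe) and \eqn{n = } the number of list genes carrying any
#' annotation.  Bonferroni correction is applied over the tested classes.
#'
#' @param genes Character vector of genes to test (should be a subset of
#'   `reference`; violations are dropped with a warning).
#' @param annotations Named list mapping class names to gene sets.
#' @param reference Character vector: the annotated reference universe.
#' @param min_size Minimum annotated class size in the reference.
#' @param alpha Threshold on the Bonferroni-adjusted p for flagging a
#'   class over-represented.
#' @return An `enrichment_result` tibble with one row per tested class:
#'   `class`, `n_list`, `n_annotated`, `class_size`, `expected`,
#'   `p_value`, `adjusted_p`, `over_represented`.
#' @export
category_overrep <- function(genes, annotations, reference,
                             min_size = 5, alpha = 0.05) {
  reference <- unique(reference)
  outside <- setdiff(genes, reference)
  if (length(outside) > 0) {
    warning(length(outside),
            " gene(s) outside the reference list dropped", call. = FALSE)
    genes <- intersect(genes, reference)
  }
  ann_ref <- lapply(annotations, intersect, reference)
  annotated_universe <- unique(unlist(ann_ref))
  n <- length(intersect(genes, annotated_universe))
  tested <- names(ann_ref)[lengths(ann_ref) >= min_size]
  if (length(tested) == 0 || n == 0) {
    return(new_enrichment_result(character(0), list(), numeric(0),
                                 numeric(0), character(0), character(0)))
  }
  rows <- purrr::map(tested, function(cl) {
    members <- ann_ref[[cl]]
    p0 <- length(members) / length(annotated_universe)
    x <- length(intersect(genes, members))
    p <- pbinom(x - 1, n, p0, lower.tail = FALSE)
    tibble::tibble(class = cl, n_list = x, n_annotated = n,
                   class_size = length(members), expected = n * p0,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "bonferroni")
  out$adjustment <- "bonferroni"
  out$n_tests <- length(tested)
  out$over_represented <- out$adjusted_p < alpha
  out <- dplyr::arrange(out, .data$p_value, .data$class)
  structure(out, class = c("enrichment_result", class(out)))
}
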