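#' Define a synthetic study scenario
#'
#' A scenario bundles every parameter of the synthetic-data generator:
#' a scale-free interactome with a planted, denser disease module, a
#' training set drawn from the module, candidate genes (unseen module
#' members plus off-module decoys), a noisy external relatedness ranking,
#' a differential-expression table enriched in the module, and functional
#' classes with tunable topological cohesion.  The defaults define the
#' study conditions used throughout the package's tests and vignette:
#' a 500-node preferential-attachment interactome (`m = 2`) carrying a
#' 30-gene module densified to internal density 0.3 (an order of magnitude
#' above the background, echoing the elevated within-module connectivity
#' disease proteins show), 10 training genes, relatedness noise 0.2,
#' differential-expression sensitivity 0.8 against a 0.05 background rate,
#' and 10 functional classes grown with cohesion 0.9.
#'
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @param n_nodes Number of interactome nodes.
#' @param m Preferential-attachment parameter: edges added per new node.
#' @param module_size Number of genes in the planted disease module.
#' @param module_density Target internal edge density of the module.
#' @param n_training Training genes sampled from the module.
#' @param n_decoys Off-module decoy genes added to the candidate set.
#' @param n_classes Number of functional classes.
#' @param class_cohesion Probability in `[0, 1]` that a class grows by
#'   claiming a neighbour of its current members rather than a random
#'   unlabelled node; 0 gives uniformly random labels.
#' @param de_sensitivity Probability that a module gene is called
#'   differentially expressed (adjusted p drawn below 0.05).
#' @param de_background Same probability for genes outside the module.
#' @param ranking_noise Gaussian noise SD added to the module-membership
#'   indicator when simulating the external relatedness score.
#' @param triadic Probability of one triadic-closure trial per node after
#'   preferential attachment (induces degree-dependent clustering).
#' @return An object of class `crohnet_scenario` (a named list).
#' @examples
#' sc <- crohnet_scenario(seed = 1, n_nodes = 100, module_size = 10)
#' net <- generate_interactome(sc)
#' @export
crohnet_scenario <- function(seed = 1L,
                             n_nodes = 500L,
                             m = 2L,
                             module_size = 30L,
                             module_density = 0.3,
                             n_training = 10L,
                             n_decoys = module_size,
                             n_classes = 10L,
                             class_cohesion = 0.9,
                             de_sensitivity = 0.8,
                             de_background = 0.05,
                             ranking_noise = 0.2,
                             triadic = 0.1) {
  sc <- list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
             m = as.integer(m), module_size = as.integer(module_size),
             module_density = module_density,
             n_training = as.integer(n_training),
             n_decoys = as.integer(n_decoys),
             n_classes = as.integer(n_classes),
             class_cohesion = class_cohesion,
             de_sensitivity = de_sensitivity,
             de_background = de_background,
             ranking_noise = ranking_noise,
             triadic = triadic)
  stopifnot(sc$n_nodes >= sc$m + 1)
  if (sc$module_size > sc$n_nodes) {
    stop("module_size must not exceed n_nodes", call. = FALSE)
  }
  if (sc$n_training > sc$module_size) {
    stop("n_training must not exceed module_size", call. = FALSE)
  }
  for (p in c("module_density", "class_cohesion", "de_sensitivity",
              "de_background")) {
    if (sc[[p]] < 0 || sc[[p]] > 1) stop(p, " must be in [0, 1]", call. = FALSE)
  }
  if (sc$ranking_noise < 0) stop("ranking_noise must be >= 0", call. = FALSE)
  structure(sc, class = "crohnet_scenario")
}

node_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a scale-free interactome
#'
#' Grows a preferential-attachment graph (each new node attaches to
#' `m` existing nodes with probability proportional to degree), then
#' applies one triadic-closure trial per node with probability
#' `scenario$triadic` (a random pair of a node's neighbours is joined),
#' which induces the degree-dependent clustering typical of biological
#' interactomes.  The result is a simple connected graph; with
#' `triadic = 0` the edge count is exactly
#' \eqn{\sum_{i=2}^{n} \min(m, i-1)}.
#'
#' @param scenario A [crohnet_scenario()].
#' @return An `interactome`.
#' @export
generate_interactome <- function(scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  set.seed(scenario$seed)
  g <- igraph::sample_pa(scenario$n_nodes, power = 1, m = scenario$m,
                         directed = FALSE, algorithm = "psumtree")
  igraph::V(g)$name <- node_ids(scenario$n_nodes)
  if (scenario$triadic > 0) {
    adj <- igraph::as_adj_list(g)
    extra_a <- character(0)
    extra_b <- character(0)
    ids <- igraph::V(g)$name
    for (v in seq_along(adj)) {
      nb <- adj[[v]]
      if (length(nb) >= 2 && runif(1) < scenario$triadic) {
        pick <- sample(length(nb), 2)
        extra_a <- c(extra_a, ids[as.integer(nb[pick[1]])])
        extra_b <- c(extra_b, ids[as.integer(nb[pick[2]])])
      }
    }
    if (length(extra_a) > 0) {
      edges <- rbind(net_edges(as_interactome(g)),
                     tibble::tibble(from = pmin(extra_a, extra_b),
                                    to = pmax(extra_a, extra_b)))
      return(as_interactome(edges, nodes = ids))
    }
  }
  as_interactome(g)
}

#' Plant a dense disease module in an interactome
#'
#' Samples `module_size` nodes and adds random edges among them until the
#' internal density reaches `module_density`, emulating the elevated
#' tendency of disease proteins to interact among themselves.
#'
#' @param net An `interactome`.
#' @param scenario A [crohnet_scenario()].
#' @return A list with elements `network` (augmented `interactome`) and
#'   `module` (character vector of module members).
#' @export
plant_module <- function(net, scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  s <- scenario$module_size
  if (s < 2) stop("module_size must be at least 2", call. = FALSE)
  set.seed(scenario$seed + 1L)
  ids <- net_nodes(net)
  module <- sort(sample(ids, s))
  pairs <- t(combn(module, 2))
  target <- ceiling(scenario$module_density * nrow(pairs))
  ekey <- paste(net_edges(net)$from, net_edges(net)$to, sep = "\r")
  present <- paste(pairs[, 1], pairs[, 2], sep = "\r") %in% ekey
  need <- target - sum(present)
  if (need > 0) {
    missing <- which(!present)
    add <- missing[sample(length(missing), need)]
    edges <- rbind(net_edges(net),
                   tibble::tibble(from = pairs[add, 1], to = pairs[add, 2]))
    net <- as_interactome(edges, nodes = ids)
  }
  list(network = net, module = module)
}

#' Draw training and candidate gene sets from a planted module
#'
#' Training genes are sampled from the module (the literature-verified
#' disease genes of a real study); candidates are the remaining module
#' members plus `n_decoys` off-module decoys, mirroring a GWAS-derived
#' candidate list that mixes true module genes with bystanders.  The two
#' sets are disjoint.
#'
#' @param net An `interactome`.
#' @param module Character vector of module members.
#' @param scenario A [crohnet_scenario()].
#' @return A list with character vectors `training` and `candidates`.
#' @export
make_training_and_candidates <- function(net, module, scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  set.seed(scenario$seed + 2L)
  training <- sort(sample(module, scenario$n_training))
  rest <- setdiff(module, training)
  off <- setdiff(net_nodes(net), module)
  decoys <- sort(sample(off, min(scenario$n_decoys, length(off))))
  list(training = training, candidates = sort(c(rest, decoys)))
}

#' Simulate an external relatedness ranking
#'
#' Stands in for a text-mining relatedness analysis: every network gene
#' receives a score equal to its module-membership indicator plus Gaussian
#' noise, and a rank-based p-value `p = rank / N` (ranks by decreasing
#' score, ties broken lexicographically).  With zero noise all module
#' genes precede all others.
#'
#' @param net An `interactome`.
#' @param module Character vector of module members.
#' @param scenario A [crohnet_scenario()].
#' @return A ranked-list tibble `(id, score, p_value)` ordered by p-value.
#' @export
simulate_relatedness_ranking <- function(net, module, scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  set.seed(scenario$seed + 3L)
  ids <- sort(net_nodes(net))
  score <- as.numeric(ids %in% module) +
    rnorm(length(ids), sd = scenario$ranking_noise)
  ord <- order(-score, ids)
  tibble::tibble(
    id = ids[ord],
    score = score[ord],
    p_value = seq_along(ids) / length(ids)
  )
}

#' Simulate a differential-expression table
#'
#' Each gene is declared differentially expressed (adjusted p drawn
#' uniformly on `[0, 0.05)`) with probability `de_sensitivity` if it is a
#' module member and `de_background` otherwise; non-DE genes draw their
#' adjusted p uniformly on `[0.05, 1]`.
#'
#' @inheritParams simulate_relatedness_ranking
#' @return A tibble `(id, p_adj)` with one row per network gene.
#' @export
simulate_de_table <- function(net, module, scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  set.seed(scenario$seed + 4L)
  ids <- sort(net_nodes(net))
  rate <- ifelse(ids %in% module, scenario$de_sensitivity,
                 scenario$de_background)
  is_de <- runif(length(ids)) < rate
  p <- ifelse(is_de, runif(length(ids), 0, 0.05 - 1e-12),
              runif(length(ids), 0.05, 1))
  tibble::tibble(id = ids, p_adj = p)
}

#' Assign functional classes with tunable topological cohesion
#'
#' Seeds one node per class and then repeatedly labels unlabelled nodes:
#' with probability `class_cohesion` a class (visited round-robin) claims
#' an unlabelled neighbour of its current members, otherwise a random
#' unlabelled node.  Cohesion 0 yields uniformly random labels (no
#' topological structure); cohesion near 1 grows classes as connected
#' patches, emulating the observation that functional classes form
#' relatively segregated sub-networks of the interactome.  Classes are
#' exclusive and partition the node set.
#'
#' @param net An `interactome`.
#' @param scenario A [crohnet_scenario()].
#' @return A named list mapping class names to character vectors of genes.
#' @export
assign_classes <- function(net, scenario) {
  stopifnot(inherits(scenario, "crohnet_scenario"))
  set.seed(scenario$seed + 5L)
  ids <- sort(net_nodes(net))
  n <- length(ids)
  k <- min(scenario$n_classes, n)
  sg <- simple_graph(net)
  adj <- lapply(igraph::as_adj_list(sg), igraph::as_ids)
  names(adj) <- igraph::V(sg)$name
  seeds <- sample(ids, k)
  members <- lapply(seq_len(k), function(i) seeds[i])
  unlab <- setdiff(ids, seeds)
  cl <- 0L
  while (length(unlab) > 0) {
    cl <- cl %% k + 1L
    pick <- NULL
    if (runif(1) < scenario$class_cohesion) {
      frontier <- intersect(unique(unlist(adj[members[[cl]]])), unlab)
      if (length(frontier) > 0) {
        pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
      }
    }
    if (is.null(pick)) {
      pick <- if (length(unlab) == 1) unlab else sample(unlab, 1)
    }
    members[[cl]] <- c(members[[cl]], pick)
    unlab <- setdiff(unlab, pick)
  }
  setNames(lapply(seq_len(k), function(i) sort(unname(members[[i]]))),
           sprintf("class%02d", seq_len(k)))
}

#' Generate every artifact of a synthetic study
#'
#' Convenience wrapper running the full generator chain and, optionally,
#' writing all artifacts in the package's file formats.
#'
#' @param scenario A [crohnet_scenario()].
#' @param dir Optional output directory; created if missing.
#' @return A list with `network`, `module`, `training`, `candidates`,
#'   `ranking`, `de_table`, `classes` and (if `dir` given) `files`.
#' @export
simulate_study <- function(scenario, dir = NULL) {
  base <- generate_interactome(scenario)
  planted <- plant_module(base, scenario)
  sets <- make_training_and_candidates(planted$network, planted$module,
                                       scenario)
  out <- list(
    network = planted$network,
    module = planted$module,
    training = sets$training,
    candidates = sets$candidates,
    ranking = simulate_relatedness_ranking(planted$network, planted$module,
                                           scenario),
    de_table = simulate_de_table(planted$network, planted$module, scenario),
    classes = assign_classes(planted$network, scenario)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      edges = file.path(dir, "interactome.tsv"),
      nodes = file.path(dir, "interactome_nodes.txt"),
      module = file.path(dir, "module.txt"),
      training = file.path(dir, "training.txt"),
      candidates = file.path(dir, "candidates.txt"),
      ranking = file.path(dir, "relatedness_ranking.tsv"),
      de_table = file.path(dir, "de_table.tsv"),
      classes = file.path(dir, "classes.gmt")
    )
    write_edge_list(out$network, files$edges, node_path = files$nodes)
    write_gene_set(out$module, files$module)
    write_gene_set(out$training, files$training)
    write_gene_set(out$candidates, files$candidates)
    write_ranked_list(out$ranking, files$ranking)
    write_de_table(out$de_table, files$de_table)
    write_annotations(out$classes, files$classes)
    out$files <- files
  }
  out
}
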