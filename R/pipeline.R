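#' Default pipeline configuration
#'
#' One structured configuration drives the whole analysis.  It contains a
#' global `seed` (every stage derives its own seed deterministically from
#' it), the synthetic scenario parameters, and one section per analysis
#' stage.  The configuration can be written to / read from YAML, so runs
#' are fully reproducible from a single file.
#'
#' @param seed Global integer seed.
#' @return A nested list of class `crohnet_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scenario = unclass(crohnet_scenario(seed = seed)),
    prioritise = list(restart = 0.5, tol = 1e-10, max_iter = 10000,
                      rule = "top_k", value = 30, p_threshold = 0.1,
                      mode = "intersection"),
    topology = list(n_random = 100),
    robustness = list(step_fraction = 0.05),
    motifs = list(k = c(3, 4), n_random = 100, z_threshold = 2,
                  swaps_per_edge = 10, participation_k = 3),
    segregation = list(min_size = 5, coverage = 0.5,
                       mode = "mean_of_ratios"),
    enrichment = list(alpha = 0.05, min_size = 5)
  ), class = "crohnet_config")
}

#' @rdname default_pipeline_config
#' @param path YAML file to read or write.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(
    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  for (sec in names(cfg)) {
    if (is.list(base[[sec]]) && is.list(cfg[[sec]])) {
      base[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    } else {
      base[[sec]] <- cfg[[sec]]
    }
  }
  base$scenario <- do.call(crohnet_scenario, base$scenario)
  base$scenario <- unclass(base$scenario)
  base
}

#' @rdname default_pipeline_config
#' @param config A `crohnet_config` list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(config, stage) {
  # deterministic per-stage seed below 2^31
  offset <- sum(utf8ToInt(stage)) %% 997L
  (config$seed * 1009L + offset) %% .Machine$integer.max
}

pipeline_stages <- function() {
  c("simulate", "prioritise", "subnetwork", "topology", "robustness",
    "motifs", "segregation", "enrichment", "report")
}

stage_outputs <- function(out_dir) {
  f <- function(...) file.path(out_dir, ...)
  list(
    simulate = c(f("interactome.tsv"), f("interactome_nodes.txt"),
                 f("module.txt"), f("training.txt"), f("candidates.txt"),
                 f("relatedness_ranking.tsv"), f("de_table.tsv"),
                 f("classes.gmt")),
    prioritise = c(f("rwr_probabilities.tsv"), f("prioritised.txt"),
                   f("prioritisation.json")),
    subnetwork = c(f("disease_edges.tsv"), f("node_roles.tsv")),
    topology = c(f("topology_comparison.tsv"), f("node_metrics.tsv"),
                 f("clustering_by_degree.tsv")),
    robustness = c(f("removal_trajectories.tsv")),
    motifs = c(f("motif_census.tsv"), f("motif_participation.tsv")),
    segregation = c(f("segregation_classes.tsv"),
                    f("segregation_prioritised.tsv")),
    enrichment = c(f("enrichment.tsv"), f("category_enrichment.tsv")),
    report = c(f("report.json"), f("report.txt"))
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on the synthetic scenario in
#' the configuration: simulate the study artifacts, prioritise by random
#' walk with restart plus external-ranking consensus, extract the disease
#' sub-network, then characterise it (topology vs an Erdős–Rényi
#' ensemble, failure-attack robustness, motif census against the
#' switching null, functional-class segregation) and compute the
#' enrichment statistics.  Every stage writes deterministic TSV/JSON
#' outputs into `out_dir` and the final report aggregates per-stage
#' summaries and a provenance manifest.  Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A `crohnet_config` list ([default_pipeline_config()]) or
#'   the path of a YAML configuration file.
#' @param out_dir Output directory (created if missing).
#' @param incremental Skip stages whose outputs already exist, provided no
#'   upstream stage was re-run; deleting an intermediate file re-runs its
#'   stage and everything downstream.
#' @param verbose Print one line per stage.
#' @return A tibble manifest: one row per stage with `stage`, `ran` and
#'   the output paths, invisibly usable for dependency checks.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, incremental = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- stage_outputs(out_dir)
  scenario <- do.call(crohnet_scenario, config$scenario)
  state <- new.env(parent = emptyenv())
  upstream_ran <- FALSE
  ran <- logical(length(pipeline_stages()))
  names(ran) <- pipeline_stages()
  log_line <- function(...) if (verbose) message(sprintf(...))

  for (stage in pipeline_stages()) {
    need <- !incremental || upstream_ran || !all(file.exists(outs[[stage]]))
    if (need) {
      run_stage(stage, config, scenario, out_dir, outs, state, log_line)
      ran[stage] <- TRUE
      upstream_ran <- TRUE
    } else {
      log_line("stage %-12s skipped (outputs present)", stage)
      load_stage(stage, outs, state)
    }
  }
  invisible(tibble::tibble(
    stage = pipeline_stages(),
    ran = unname(ran),
    outputs = unname(vapply(outs, paste, character(1), collapse = ";"))
  ))
}

# reload the artifacts later stages need when a stage is skipped
load_stage <- function(stage, outs, state) {
  o <- outs[[stage]]
  switch(stage,
    simulate = {
      state$network <- read_edge_list(o[1], node_path = o[2])
      state$module <- read_gene_set(o[3])
      state$training <- read_gene_set(o[4])
      state$candidates <- read_gene_set(o[5])
      state$ranking <- read_ranked_list(o[6])
      state$de_table <- read_de_table(o[7])
      state$classes <- read_annotations(o[8])
    },
    prioritise = {
      state$prioritised <- read_gene_set(o[2])
    },
    subnetwork = {
      state$disease <- read_edge_list(o[1])
      roles <- readr::read_tsv(o[2], col_types = "cc", progress = FALSE)
      attr(state$disease, "node_roles") <- roles
    },
    invisible(NULL)
  )
}

run_stage <- function(stage, config, scenario, out_dir, outs, state,
                      log_line) {
  o <- outs[[stage]]
  switch(stage,
    simulate = {
      study <- simulate_study(scenario, dir = out_dir)
      state$network <- study$network
      state$module <- study$module
      state$training <- study$training
      state$candidates <- study$candidates
      state$ranking <- study$ranking
      state$de_table <- study$de_table
      state$classes <- study$classes
      log_line("stage %-12s %d nodes, %d edges", stage,
               igraph::vcount(study$network),
               igraph::ecount(study$network))
    },
    prioritise = {
      pc <- config$prioritise
      res <- rwr(state$network, state$training, r = pc$restart,
                 tol = pc$tol, max_iter = pc$max_iter)
      sel <- select_by_steady_state(res, state$candidates,
                                    rule = pc$rule, value = pc$value)
      ext <- select_external(state$ranking, pc$p_threshold)
      cons <- consensus(sel, ext, state$training, mode = pc$mode,
                        nodes = net_nodes(state$network))
      state$prioritised <- cons$consensus
      readr::write_tsv(tidy(res), o[1], progress = FALSE)
      write_gene_set(cons$consensus, o[2])
      jsonlite::write_json(list(
        parameters = pc,
        iterations = res$iterations,
        converged = res$converged,
        n_rwr_selected = length(cons$rwr_selected),
        n_external_selected = length(cons$external_selected),
        n_consensus = length(cons$consensus)
      ), o[3], auto_unbox = TRUE, pretty = TRUE, digits = NA)
      log_line("stage %-12s %d consensus genes", stage,
               length(cons$consensus))
    },
    subnetwork = {
      state$disease <- extract_disease_network(state$network,
                                               state$prioritised)
      write_edge_list(state$disease, o[1])
      readr::write_tsv(node_roles(state$disease), o[2], progress = FALSE)
      log_line("stage %-12s %d nodes, %d edges", stage,
               igraph::vcount(state$disease),
               igraph::ecount(state$disease))
    },
    topology = {
      rep <- er_ensemble_compare(state$disease,
                                 n_random = config$topology$n_random,
                                 seed = stage_seed(config, stage))
      readr::write_tsv(rep$comparison, o[1], progress = FALSE)
      readr::write_tsv(rep$per_node, o[2], progress = FALSE)
      readr::write_tsv(clustering_by_degree(state$disease), o[3],
                       progress = FALSE)
      state$topology <- rep
      log_line("stage %-12s %d metrics", stage, nrow(rep$comparison))
    },
    robustness = {
      sf <- config$robustness$step_fraction
      seed <- stage_seed(config, stage)
      curves <- purrr::map_dfr(
        c("random", "degree_desc", "degree_asc"),
        function(s) {
          dplyr::mutate(tibble::as_tibble(
            removal_trajectory(state$disease, s, sf, seed = seed)),
            strategy = s)
        })
      gs <- removal_trajectory(state$disease, "gene_set", sf, seed = seed,
                               gene_set = state$prioritised)
      curves <- dplyr::bind_rows(
        curves, dplyr::mutate(tibble::as_tibble(gs),
                              strategy = "prioritised_set"))
      readr::write_tsv(curves, o[1], progress = FALSE)
      state$robustness <- curves
      log_line("stage %-12s %d trajectory rows", stage, nrow(curves))
    },
    motifs = {
      mc <- config$motifs
      seed <- stage_seed(config, stage)
      censuses <- purrr::map(mc$k, function(k) {
        motif_zscores(state$disease, k, n_random = mc$n_random,
                      z_threshold = mc$z_threshold,
                      swaps_per_edge = mc$swaps_per_edge,
                      seed = seed + k)
      })
      names(censuses) <- as.character(mc$k)
      census_tbl <- dplyr::bind_rows(purrr::imap(
        censuses, function(cen, k) {
          dplyr::mutate(tibble::as_tibble(cen), k = as.integer(k))
        }))
      readr::write_tsv(census_tbl, o[1], progress = FALSE)
      pk <- as.character(mc$participation_k)
      cen <- if (pk %in% names(censuses)) {
        censuses[[pk]]
      } else {
        motif_zscores(state$disease, as.integer(pk),
                      n_random = mc$n_random,
                      z_threshold = mc$z_threshold,
                      swaps_per_edge = mc$swaps_per_edge,
                      seed = seed + as.integer(pk))
      }
      part <- motif_participation(
        state$disease, cen,
        intersect(state$prioritised, net_nodes(state$disease)))
      readr::write_tsv(part, o[2], progress = FALSE)
      state$motifs <- census_tbl
      state$participation <- part
      log_line("stage %-12s %d motif calls", stage,
               sum(census_tbl$call == "motif"))
    },
    segregation = {
      sg <- config$segregation
      classes_tbl <- segregate_classes(state$disease, state$classes,
                                       min_size = sg$min_size,
                                       coverage = sg$coverage,
                                       mode = sg$mode)
      readr::write_tsv(classes_tbl, o[1], progress = FALSE)
      pri_in <- intersect(state$prioritised, net_nodes(state$disease))
      pri <- list_segregation(state$disease, pri_in,
                              coverage = sg$coverage, mode = sg$mode)
      readr::write_tsv(
        dplyr::mutate(glance(pri), class = "prioritised_list",
                      .before = 1),
        o[2], progress = FALSE)
      state$segregation <- classes_tbl
      state$segregation_prioritised <- pri
      log_line("stage %-12s prioritised-list S = %.2f", stage, pri$index)
    },
    enrichment = {
      ec <- config$enrichment
      hubs <- identify_hubs(state$network)
      n_pop <- length(net_nodes(state$network))
      pri <- intersect(state$prioritised, net_nodes(state$network))
      dis <- net_nodes(state$disease)
      rows <- dplyr::bind_rows(
        dplyr::mutate(hypergeom_overrep(
          n_pop, length(hubs), length(pri),
          length(intersect(pri, hubs))), population = "prioritised"),
        dplyr::mutate(hypergeom_overrep(
          n_pop, length(hubs), length(dis),
          length(intersect(dis, hubs))), population = "disease_network"),
        dplyr::mutate(
          de_enrichment(pri, state$de_table, alpha = ec$alpha),
          population = "prioritised")
      )
      readr::write_tsv(rows, o[1], progress = FALSE)
      cats <- category_overrep(pri, state$classes,
                               reference = net_nodes(state$network),
                               min_size = ec$min_size, alpha = ec$alpha)
      readr::write_tsv(cats, o[2], progress = FALSE)
      state$enrichment <- rows
      state$categories <- cats
      log_line("stage %-12s %d over-represented categories", stage,
               sum(cats$over_represented))
    },
    report = {
      manifest <- basename(unlist(outs[setdiff(names(outs), "report")],
                                  use.names = FALSE))
      summary <- list(
        config = unclass(config),
        package_version = as.character(utils::packageVersion("crohnet")),
        interactome = list(nodes = igraph::vcount(state$network),
                           edges = igraph::ecount(state$network)),
        prioritised = length(state$prioritised),
        disease_network = list(
          nodes = igraph::vcount(state$disease),
          edges = igraph::ecount(state$disease),
          density_ratio = density_ratio(state$disease, state$network)
        ),
        motifs = if (!is.null(state$motifs)) {
          list(n_motif = sum(state$motifs$call == "motif"),
               n_anti_motif = sum(state$motifs$call == "anti-motif"))
        },
        segregation_prioritised =
          if (!is.null(state$segregation_prioritised)) {
            state$segregation_prioritised$index
          },
        files = manifest
      )
      jsonlite::write_json(summary, o[1], auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      txt <- c(
        "crohnet pipeline report",
        sprintf("interactome: %d nodes, %d edges",
                igraph::vcount(state$network),
                igraph::ecount(state$network)),
        sprintf("prioritised genes: %d", length(state$prioritised)),
        sprintf("disease network: %d nodes, %d edges (density ratio %.2f)",
                igraph::vcount(state$disease),
                igraph::ecount(state$disease),
                density_ratio(state$disease, state$network)),
        sprintf("output files: %d", length(manifest))
      )
      readr::write_lines(txt, o[2])
      log_line("stage %-12s %d files in manifest", stage, length(manifest))
    }
  )
  invisible(NULL)
}
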