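test_that("preferential attachment edge count follows the construction rule", {
  sc <- crohnet_scenario(seed = 1, n_nodes = 100, m = 2, triadic = 0)
  net <- generate_interactome(sc)
  # each new node i attaches to min(m, i - 1) existing nodes
  expected_edges <- sum(pmin(2, seq_len(100) - 1))
  expect_equal(nrow(net_edges(net)), expected_edges)  # 197 for n=100, m=2
  expect_equal(length(net_nodes(net)), 100)
  expect_true(igraph::is_connected(net))
  expect_true(igraph::is_simple(net))
})

test_that("the generator is deterministic under the scenario seed", {
  sc <- crohnet_scenario(seed = 7, n_nodes = 120)
  expect_equal(net_edges(generate_interactome(sc)),
               net_edges(generate_interactome(sc)))
  sts <- simulate_study(sc)
  sts2 <- simulate_study(sc)
  expect_equal(sts$ranking, sts2$ranking)
  expect_equal(sts$de_table, sts2$de_table)
  expect_equal(sts$classes, sts2$classes)
})

test_that("degree distributions are heavy-tailed", {
  for (seed in 1:10) {
    sc <- crohnet_scenario(seed = seed, n_nodes = 5000, m = 3, triadic = 0)
    deg <- igraph::degree(generate_interactome(sc))
    expect_gt(max(deg), 10 * mean(deg))
  }
})

test_that("module planting reaches the requested internal density", {
  sc <- crohnet_scenario(seed = 3, n_nodes = 100, module_size = 10,
                         module_density = 1.0)
  planted <- plant_module(generate_interactome(sc), sc)
  sub <- igraph::induced_subgraph(planted$network, planted$module)
  expect_equal(igraph::ecount(sub), 45)  # a 10-clique

  sc2 <- crohnet_scenario(seed = 4, n_nodes = 500, module_size = 30,
                          module_density = 0.3)
  planted2 <- plant_module(generate_interactome(sc2), sc2)
  sub2 <- igraph::induced_subgraph(planted2$network, planted2$module)
  expect_gte(igraph::ecount(sub2), ceiling(0.3 * choose(30, 2)))

  # density target already met: nothing is added
  sc3 <- crohnet_scenario(seed = 5, n_nodes = 60, module_size = 5,
                          n_training = 2, module_density = 0)
  base <- generate_interactome(sc3)
  planted3 <- plant_module(base, sc3)
  expect_equal(net_edges(planted3$network), net_edges(base))

  expect_error(plant_module(base, local({
    s <- crohnet_scenario(seed = 1, n_nodes = 60, module_size = 2,
                          n_training = 1)
    s$module_size <- 1L
    s
  })), "at least 2")
})

test_that("global density stays close to the pre-planting density", {
  sc <- crohnet_scenario(seed = 11)  # module 30 of 500
  base <- generate_interactome(sc)
  planted <- plant_module(base, sc)
  expect_lt(net_density(planted$network), 1.5 * net_density(base))
})

test_that("training and candidate sets are disjoint and well-composed", {
  sc <- crohnet_scenario(seed = 2)
  study <- simulate_study(sc)
  expect_length(intersect(study$training, study$candidates), 0)
  expect_true(all(study$training %in% study$module))
  # candidates = unseen module members + configured decoys
  unseen <- setdiff(study$module, study$training)
  expect_true(all(unseen %in% study$candidates))
  n_decoys <- sum(!study$candidates %in% study$module)
  expect_equal(n_decoys, sc$n_decoys)
})

test_that("noise-free relatedness ranking puts the module first", {
  sc <- crohnet_scenario(seed = 6, n_nodes = 200, module_size = 20,
                         n_training = 5, ranking_noise = 0)
  planted <- plant_module(generate_interactome(sc), sc)
  rl <- simulate_relatedness_ranking(planted$network, planted$module, sc)
  n_mod <- length(planted$module)
  expect_setequal(rl$id[seq_len(n_mod)], planted$module)
  # p-values are the rank transform
  expect_equal(rl$p_value, seq_len(nrow(rl)) / nrow(rl))
})

test_that("noisy relatedness scores separate the module (AUROC)", {
  aucs <- vapply(1:10, function(seed) {
    sc <- crohnet_scenario(seed = seed, ranking_noise = 0.2)
    planted <- plant_module(generate_interactome(sc), sc)
    rl <- simulate_relatedness_ranking(planted$network, planted$module, sc)
    oracle_auc(rl$score, rl$id %in% planted$module)
  }, numeric(1))
  expect_gte(median(aucs), 0.9)
})

test_that("DE table has the designed sensitivity and background", {
  sc <- crohnet_scenario(seed = 8, n_nodes = 300, module_size = 25,
                         de_sensitivity = 1, de_background = 0)
  planted <- plant_module(generate_interactome(sc), sc)
  de <- simulate_de_table(planted$network, planted$module, sc)
  expect_setequal(de$id[de$p_adj < 0.05], planted$module)
  expect_true(all(de$p_adj >= 0 & de$p_adj <= 1))

  sc2 <- crohnet_scenario(seed = 9)
  planted2 <- plant_module(generate_interactome(sc2), sc2)
  de2 <- simulate_de_table(planted2$network, planted2$module, sc2)
  n_mod <- length(planted2$module)
  n_bg <- nrow(de2) - n_mod
  expected <- sc2$de_sensitivity * n_mod + sc2$de_background * n_bg
  sd3 <- 3 * sqrt(sc2$de_sensitivity * (1 - sc2$de_sensitivity) * n_mod +
                    sc2$de_background * (1 - sc2$de_background) * n_bg)
  observed <- sum(de2$p_adj < 0.05)
  expect_lt(abs(observed - expected), sd3)
})

test_that("exclusive classes partition the node set", {
  sc <- crohnet_scenario(seed = 10, n_nodes = 150, n_classes = 6)
  net <- generate_interactome(sc)
  classes <- assign_classes(net, sc)
  expect_length(classes, 6)
  all_members <- unlist(classes)
  expect_equal(sort(unname(all_members)), sort(net_nodes(net)))
  expect_false(anyDuplicated(all_members) > 0)
})
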