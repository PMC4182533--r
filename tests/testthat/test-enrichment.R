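test_that("hubs are the nodes with degree strictly above the mean", {
  ring <- as_interactome(igraph::make_ring(8))
  expect_length(identify_hubs(ring), 0)       # regular graph: no hubs
  star9 <- star_net(9, centre = "c")          # mean degree 1.8
  expect_equal(identify_hubs(star9), "c")
  for (seed in 1:10) {
    net <- random_net(25, 0.2, seed = seed)
    deg <- igraph::degree(net)
    expect_setequal(identify_hubs(net),
                    names(deg)[deg > mean(deg)])
  }
})

test_that("hypergeometric upper tail matches direct enumeration", {
  expect_equal(hypergeom_overrep(10, 4, 5, 4)$p_value, 6 / 252)
  expect_equal(hypergeom_overrep(30, 10, 8, 0)$p_value, 1)
  set.seed(2)
  for (i in 1:25) {
    pop <- sample(5:20, 1)
    K <- sample(1:pop, 1)
    n <- sample(1:pop, 1)
    x <- sample(max(0, n + K - pop):min(n, K), 1)
    expect_equal(hypergeom_overrep(pop, K, n, x)$p_value,
                 oracle_hypergeom(pop, K, n, x), tolerance = 1e-12)
  }
  expect_error(hypergeom_overrep(10, 4, 5, 5), "inconsistent")
})

test_that("Fisher two-sided p matches full-table enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value,
               2 / 252, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:30) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 oracle_fisher_two_sided(tab), tolerance = 1e-9)
  }
  # one-sided tail is the hypergeometric upper tail on cell [1,1]
  tab <- matrix(c(6, 2, 3, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab, alternative = "greater")$p_value,
               oracle_hypergeom(20, 9, 8, 6), tolerance = 1e-12)
})

test_that("binomial category test matches the direct sum and corrects", {
  ref <- sprintf("r%03d", 1:100)
  ann <- list(big = ref[1:10], small = ref[1:2],
              all = ref)
  genes <- ref[c(1:5, 21:25)]
  res <- category_overrep(genes, ann, ref, min_size = 5)
  expect_false("small" %in% res$class)          # below min_size
  row <- res[res$class == "big", ]
  expect_equal(row$p_value, oracle_binom(5, 10, 0.1), tolerance = 1e-12)
  # P(X >= 5), X ~ Bin(10, 0.1): the k = 5 term alone is 1.488e-3 and the
  # full upper tail sums to 1.635e-3
  expect_equal(oracle_binom(5, 10, 0.1), 0.0016349374, tolerance = 1e-7)
  # a class covering the whole reference is never over-represented
  expect_equal(res$p_value[res$class == "all"], 1)
  # Bonferroni: adjusted = min(1, m p), m = number of tested classes
  expect_equal(res$adjusted_p, pmin(1, nrow(res) * res$p_value))
  expect_true(all(res$adjusted_p >= res$p_value))
})

test_that("category test keeps its nominal type-I error under the null", {
  ref <- sprintf("u%03d", 1:400)
  set.seed(11)
  ann <- lapply(setNames(1:8, sprintf("c%d", 1:8)),
                function(i) sample(ref, 80))
  rate <- mean(vapply(1:100, function(i) {
    genes <- sample(ref, 60)
    res <- category_overrep(genes, ann, ref, min_size = 5)
    mean(res$p_value < 0.05)
  }, numeric(1)))
  expect_lt(rate, 0.08)
  expect_gt(rate, 0.015)
})

test_that("genes outside the reference are dropped with a warning", {
  ref <- sprintf("r%03d", 1:50)
  ann <- list(c1 = ref[1:20])
  expect_warning(res <- category_overrep(c(ref[1:5], "alien"), ann, ref),
                 "outside the reference")
  expect_equal(res$n_annotated, 5)
})

test_that("DE enrichment builds the right 2x2 table over the universe", {
  de <- tibble::tibble(id = sprintf("g%02d", 1:40),
                       p_adj = c(rep(0.01, 10), rep(0.5, 30)))
  pri <- sprintf("g%02d", 1:8)           # 8 prioritised, all DE
  res <- de_enrichment(pri, de)
  expect_equal(unlist(res[c("a", "b", "c", "d")], use.names = FALSE),
               c(8, 0, 2, 30))
  expect_equal(res$a + res$b + res$c + res$d, 40)
  expect_equal(res$p_value,
               oracle_fisher_two_sided(matrix(c(8, 0, 2, 30), 2,
                                              byrow = TRUE)),
               tolerance = 1e-9)
})

test_that("the planted module's DE signal is detected across seeds", {
  hits <- vapply(1:10, function(seed) {
    sc <- crohnet_scenario(seed = seed)
    study <- simulate_study(sc)
    res <- de_enrichment(study$module, study$de_table)
    res$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("hub-neighbour test compares a protein's neighbours to the proteome", {
  # proteome: two hubs h1, h2; protein x adjacent to both; y adjacent to none
  edges <- dplyr::bind_rows(
    tibble::tibble(from = "h1", to = sprintf("a%02d", 1:8)),
    tibble::tibble(from = "h2", to = sprintf("b%02d", 1:8)),
    tibble::tibble(from = "x", to = c("h1", "h2")),
    tibble::tibble(from = "y", to = c("a01", "b01"))
  )
  proteome <- as_interactome(edges)
  hubs <- identify_hubs(proteome)
  expect_true(all(c("h1", "h2") %in% hubs))
  res <- hub_neighbour_test(proteome, "x", hubs, proteome)
  # column marginal equals the hub count (focal x is not a hub)
  expect_equal(res$a + res$c, length(hubs))
  expect_lt(res$p_value, 0.05)
  res_y <- hub_neighbour_test(proteome, "y", hubs, proteome)
  expect_gt(res_y$p_value, res$p_value)
  lone <- as_interactome(edges, nodes = "zz")
  expect_error(hub_neighbour_test(lone, "zz", hubs, proteome),
               "no neighbours")
})

test_that("enrichment results carry consistent directions and counts", {
  over <- hypergeom_overrep(100, 20, 10, 8)
  expect_equal(over$direction, "over")
  under <- hypergeom_overrep(100, 20, 10, 0)
  expect_equal(under$direction, "under")
  tab <- matrix(c(9, 1, 1, 9), 2)
  expect_equal(fisher_exact_2x2(tab)$direction, "over")
})
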