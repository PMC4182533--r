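test_that("canonical ids reproduce the decodable anchors", {
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(canonical_subgraph_id(path3), 78L)
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(canonical_subgraph_id(tri), 238L)
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(canonical_subgraph_id(k4), 31710L)
})

test_that("canonical ids are invariant under node permutation", {
  set.seed(1)
  for (k in c(3, 4)) {
    for (rep in 1:20) {
      a <- matrix(0L, k, k)
      pairs <- which(upper.tri(a))
      on <- pairs[runif(length(pairs)) < 0.6]
      a[on] <- 1L
      a <- a + t(a)
      p <- sample(k)
      expect_equal(canonical_subgraph_id(a[p, p]),
                   canonical_subgraph_id(a))
    }
  }
})

test_that("simple fixtures are classified correctly", {
  tri <- as_interactome(tibble::tibble(from = c("a", "b", "c"),
                                       to = c("b", "c", "a")))
  cen <- subgraph_census(tri, 3)
  expect_equal(cen$count[cen$id == 238], 1)
  expect_equal(sum(cen$count), 1)

  sq <- as_interactome(tibble::tibble(from = c("a", "b", "c", "d"),
                                      to = c("b", "c", "d", "a")))
  cen4 <- subgraph_census(sq, 4)
  expect_equal(sum(cen4$count), 1)           # one connected 4-subgraph
  cycle_id <- canonical_subgraph_id(matrix(c(0, 1, 0, 1,
                                             1, 0, 1, 0,
                                             0, 1, 0, 1,
                                             1, 0, 1, 0), 4, 4))
  expect_equal(cen4$count[cen4$id == cycle_id], 1)

  expect_error(subgraph_census(tri, 5), "k must be")
})

test_that("census equals the brute-force all-combinations oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(8:25, 1)
    net <- random_net(n, runif(1, 0.1, 0.35), seed = seed)
    for (k in c(3, 4)) {
      got <- subgraph_census(net, k)
      oracle <- oracle_census(net, k)
      got_nonzero <- got[got$count > 0, ]
      expect_equal(
        setNames(got_nonzero$count, as.character(got_nonzero$id)),
        unclass(oracle[order(as.integer(names(oracle)))])
      )
      expect_equal(sum(got$count), sum(oracle))
    }
  }
})

test_that("edge switching preserves the degree multiset every draw", {
  for (seed in 1:10) {
    net <- random_net(30, 0.15, seed = seed + 30)
    r <- switch_randomize(net, swaps_per_edge = 10, seed = seed)
    expect_equal(sort(unname(igraph::degree(r))),
                 sort(unname(igraph::degree(net))))
  }
  # a triangle admits no valid swap
  tri <- as_interactome(tibble::tibble(from = c("a", "b", "c"),
                                       to = c("b", "c", "a")))
  expect_equal(net_edges(switch_randomize(tri, 10, seed = 1)),
               net_edges(tri))
  # but a sizeable random graph is almost surely rewired
  big <- as_interactome(igraph::sample_gnm(100, 300))
  moved <- vapply(1:5, function(s) {
    e1 <- net_edges(big)
    e2 <- net_edges(switch_randomize(big, 10, seed = s))
    !identical(e1, e2)
  }, logical(1))
  expect_true(all(moved))
})

test_that("a graph drawn from its own null has no motifs", {
  net <- as_interactome(igraph::sample_gnm(80, 200))
  net <- switch_randomize(net, 10, seed = 42)
  for (k in c(3, 4)) {
    cen <- motif_zscores(net, k, n_random = 50, seed = 7)
    z <- cen$z[!is.na(cen$z)]
    expect_true(all(abs(z) < 3))
  }
})

test_that("planted triangles are detected as a motif", {
  set.seed(13)
  base <- igraph::sample_gnm(120, 240)
  igraph::V(base)$name <- sprintf("v%03d", 1:120)
  edges <- net_edges(as_interactome(base))
  extra <- purrr::map_dfr(1:50, function(i) {
    trio <- sample(sprintf("v%03d", 1:120), 3)
    pairs <- t(combn(sort(trio), 2))
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  })
  net <- as_interactome(dplyr::bind_rows(edges, extra))
  cen <- motif_zscores(net, 3, n_random = 50, seed = 3)
  expect_gte(cen$z[cen$id == 238], 2)
  expect_equal(cen$call[cen$id == 238], "motif")
  # determinism under the seed
  cen2 <- motif_zscores(net, 3, n_random = 50, seed = 3)
  expect_equal(tibble::as_tibble(cen), tibble::as_tibble(cen2))
})

test_that("motif participation counts instances containing each gene", {
  # hub of planted triangles: triangles all pass through "hub"
  tri_edges <- purrr::map_dfr(1:6, function(i) {
    a <- sprintf("t%da", i); b <- sprintf("t%db", i)
    tibble::tibble(from = c("hub", "hub", a),
                   to = c(a, b, b))
  })
  net <- as_interactome(tri_edges)
  census <- motif_zscores(net, 3, n_random = 30, seed = 1)
  census$call[census$id == 238] <- "motif"  # pin the class of interest
  census$call[census$id != 238] <- "neutral"
  part <- motif_participation(net, census, net_nodes(net))
  expect_equal(part$id[1], "hub")  # hub participates in all 6 triangles
  expect_equal(part$participation[part$id == "hub"], 6L)
  # double-counting identity: total participation = k * instances
  expect_equal(sum(part$participation), 3 * 6)
  # a spoke gene sits in exactly one triangle
  solo <- motif_participation(net, census, "t6b")
  expect_equal(solo$participation, 1L)
})

test_that("participation restricted to motif calls can be empty", {
  pathg <- path_net(c("a", "b", "c", "d"))
  cen <- motif_zscores(pathg, 3, n_random = 20, seed = 2)
  cen$call[] <- "neutral"
  part <- motif_participation(pathg, cen, c("a", "b"))
  expect_equal(part$participation, c(0L, 0L))
})
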