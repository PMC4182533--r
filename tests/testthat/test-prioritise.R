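test_that("restart-only walk returns the restart vector exactly", {
  net <- random_net(20, 0.2, seed = 1)
  training <- net_nodes(net)[1:4]
  res <- rwr(net, training, r = 1)
  expected <- ifelse(net_nodes(net) %in% training, 0.25, 0)
  expect_equal(res$probabilities$prob, expected)
  expect_equal(rwr_exact(net, training, r = 1)$probabilities$prob, expected)
})

test_that("stationary state on the 3-path matches the linear-system solution", {
  net <- path_net(c("a", "b", "c"))
  # hand solve of (I - 0.5 W) p = 0.5 e with column-normalised W:
  # p_a = p_b/4 + 1/2, p_b = (p_a + p_c)/2, p_c = p_b/4  =>  (7, 4, 1)/12
  hand <- c(7, 4, 1) / 12
  ex <- rwr_exact(net, "a", r = 0.5)
  expect_equal(ex$probabilities$prob, hand, tolerance = 1e-12)
  it <- rwr(net, "a", r = 0.5)
  expect_true(it$converged)
  expect_lt(sum(abs(it$probabilities$prob - hand)), 1e-8)
})

test_that("iterative solver agrees with the direct solve on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:200, 1)
    net <- random_net(n, p = min(1, 3 / n + 0.05), seed = seed)
    training <- sample(net_nodes(net), max(1, n %/% 20))
    it <- rwr(net, training, r = 0.5, tol = 1e-12)
    ex <- rwr_exact(net, training, r = 0.5)
    expect_lt(sum(abs(it$probabilities$prob - ex$probabilities$prob)),
              1e-8)
    expect_equal(sum(it$probabilities$prob), 1, tolerance = 1e-9)
  }
})

test_that("probability mass is conserved at every iteration", {
  net <- random_net(40, 0.1, seed = 3)
  training <- net_nodes(net)[1:3]
  # cap the iteration count at several points and check the running sum
  for (iters in c(1, 2, 5, 20)) {
    res <- rwr(net, training, r = 0.3, tol = 0, max_iter = iters)
    expect_equal(res$iterations, iters)
    expect_equal(sum(res$probabilities$prob), 1, tolerance = 1e-9)
  }
})

test_that("isolated training genes hold their mass (no leakage)", {
  net <- as_interactome(tibble::tibble(from = "a", to = "b"),
                        nodes = c("a", "b", "z"))
  res <- rwr(net, c("a", "z"), r = 0.5)
  expect_equal(sum(res$probabilities$prob), 1, tolerance = 1e-9)
  # walker mass stays within components containing training genes
  probs <- setNames(res$probabilities$prob, res$probabilities$id)
  expect_gt(probs[["z"]], 0)
})

test_that("rwr errors when no training gene is in the network", {
  net <- path_net()
  expect_error(rwr(net, "missing"), "training")
  expect_error(rwr(net, "a", r = 0), "restart")
})

test_that("node relabelling permutes the stationary state identically", {
  net <- random_net(15, 0.25, seed = 5)
  training <- net_nodes(net)[1:2]
  p1 <- rwr_exact(net, training, r = 0.4)$probabilities
  relabel <- setNames(sprintf("z%02d", rev(seq_along(net_nodes(net)))),
                      net_nodes(net))
  edges <- net_edges(net)
  net2 <- as_interactome(tibble::tibble(from = relabel[edges$from],
                                        to = relabel[edges$to]))
  p2 <- rwr_exact(net2, relabel[training], r = 0.4)$probabilities
  expect_equal(setNames(p2$prob, p2$id)[relabel[p1$id]],
               setNames(p1$prob, relabel[p1$id]))
})

test_that("raising the restart probability concentrates mass on training", {
  for (seed in 1:3) {
    net <- random_net(30, 0.15, seed = seed)
    training <- net_nodes(net)[1:3]
    mass <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r) {
      p <- rwr_exact(net, training, r)$probabilities
      sum(p$prob[p$id %in% training])
    }, numeric(1))
    expect_true(all(diff(mass) > 0))
  }
})

test_that("steady-state selection ranks, breaks ties and warns", {
  net <- path_net(c("a", "b", "c", "d"))
  res <- rwr(net, "a", r = 0.5)
  cands <- c("b", "c", "d")
  expect_equal(select_by_steady_state(res, cands, "top_k", 3),
               sort(cands))  # k = |candidates| is the identity
  expect_equal(select_by_steady_state(res, cands, "prob_threshold", 0),
               sort(cands))  # all have positive mass on a path
  expect_warning(sel <- select_by_steady_state(res, cands, "top_k", 10),
                 "exceeds")
  expect_equal(sel, sort(cands))
  top1 <- select_by_steady_state(res, cands, "top_k", 1)
  expect_equal(top1, "b")  # nearest to the training gene
})

test_that("external selection is a strict p-value cut", {
  rl <- tibble::tibble(id = sprintf("g%03d", 1:200),
                       score = 200:1,
                       p_value = (1:200) / 200)
  expect_length(select_external(rl, 1 + 1e-9), 200)
  # p exactly at the threshold is excluded: p = 0.1 is rank 20
  expect_length(select_external(rl, 0.1), 19)
  # synthetic ranking with 40 entries below 0.1
  rl2 <- tibble::tibble(id = sprintf("h%03d", 1:200), score = 0,
                        p_value = c(seq(0.001, 0.099, length.out = 40),
                                    seq(0.2, 1, length.out = 160)))
  expect_length(select_external(rl2, 0.1), 40)
})

test_that("consensus combines the selections with the training set", {
  expect_equal(consensus(c("a", "b"), c("c", "d"), c("t1"))$consensus,
               "t1")  # disjoint selections
  expect_equal(consensus(c("a", "b"), c("a", "b"), "t1")$consensus,
               sort(c("a", "b", "t1")))
  # constructed overlap: |A| = 212, |B| = 174, |A∩B| = 80, training 30
  A <- sprintf("s%03d", 1:212)
  B <- sprintf("s%03d", 133:306)   # overlap 133..212 = 80 genes
  Tset <- sprintf("t%02d", 1:30)
  res <- consensus(A, B, Tset)
  expect_length(res$consensus, 80 + 30)
  expect_length(consensus(A, B, Tset, mode = "union")$consensus,
                length(union(A, B)) + 30)
  # restriction to network nodes
  res2 <- consensus(A, B, Tset, nodes = c(A[150], Tset[1]))
  expect_setequal(res2$consensus, c(A[150], Tset[1]))
})

test_that("prioritisation tidiers summarise the result", {
  res <- consensus(c("a", "b"), c("b", "c"), "t")
  td <- tidy(res)
  expect_setequal(td$id, c("b", "t"))
  expect_true(all(c("in_rwr", "in_external", "in_training") %in%
                    names(td)))
  g <- glance(res)
  expect_equal(g$n_consensus, 2)
  expect_equal(g$mode, "intersection")
})
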