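# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (brute force, enumeration) so it
# exercises none of the package's own code paths beyond trivial
# constructors.

# deterministic Erdos-Renyi-ish fixture as an edge tibble
random_edge_table <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
}

random_net <- function(n, p = 0.15, seed = 1) {
  as_interactome(random_edge_table(n, p, seed))
}

path_net <- function(ids = c("a", "b", "c")) {
  as_interactome(tibble::tibble(from = ids[-length(ids)], to = ids[-1]))
}

star_net <- function(n_leaves = 5, centre = "hub") {
  as_interactome(tibble::tibble(from = centre,
                                to = sprintf("l%02d", seq_len(n_leaves))))
}

# ---- graph oracles -------------------------------------------------------

# adjacency list from an edge tibble, without igraph
oracle_adj <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# single-source BFS distances, plain R
oracle_bfs <- function(edges, source, nodes = NULL) {
  adj <- oracle_adj(edges, nodes)
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier])),
                   names(dist)[is.finite(dist)])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# connected components by union-find, plain R
oracle_components <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# brute-force census of connected induced k-subgraphs over all C(n, k)
# node combinations, keyed by canonical_subgraph_id (the id function is
# itself pinned by hand-decodable anchors elsewhere)
oracle_census <- function(net, k) {
  edges <- net_edges(net)
  nodes <- sort(net_nodes(net))
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    amat[edges$from[i], edges$to[i]] <- 1L
    amat[edges$to[i], edges$from[i]] <- 1L
  }
  connected <- function(a) {
    seen <- 1L
    repeat {
      nxt <- unique(c(seen, which(rowSums(a[, seen, drop = FALSE]) > 0)))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == nrow(a)
  }
  counts <- integer(0)
  if (length(nodes) >= k) {
    combs <- combn(length(nodes), k)
    for (j in seq_len(ncol(combs))) {
      a <- amat[combs[, j], combs[, j]]
      if (connected(a)) {
        id <- as.character(canonical_subgraph_id(a))
        counts[id] <- (if (is.na(counts[id])) 0L else counts[id]) + 1L
      }
    }
  }
  counts
}

# ---- exact-test oracles --------------------------------------------------

# upper-tail hypergeometric by direct combinatorial sum
oracle_hypergeom <- function(pop, K, n, x) {
  js <- x:min(n, K)
  sum(choose(K, js) * choose(pop - K, n - js)) / choose(pop, n)
}

# two-sided Fisher p by enumerating every table with the fixed marginals
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail binomial by direct sum
oracle_binom <- function(x, n, p) {
  ks <- x:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

# rank-based AUROC (Wilcoxon statistic), independent of any package code
oracle_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
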