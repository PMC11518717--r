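test_that("abundance filter applies a strict cumulative threshold", {
  x <- rbind(a = c(50, 49), b = c(50, 50), c = c(51, 50))
  colnames(x) <- c("s1", "s2")
  m <- count_matrix(x, c(s1 = "g", s2 = "g"), "CPM")
  expect_equal(abundance_filter(m, 100)$taxa, "c")   # 99/100/101 boundary
  expect_setequal(abundance_filter(m, 0)$taxa, c("a", "b", "c"))

  set.seed(41)
  r <- cpm_normalize(random_count_matrix(50, c(A = 3, B = 3)))
  thr <- stats::median(rowSums(r$counts))
  expect_equal(length(abundance_filter(r, thr)$taxa),
               sum(rowSums(r$counts) > thr))
})

test_that("correlation edges match a brute-force all-pairs oracle", {
  n <- 12
  x <- rbind(x1 = 1:n, x2 = 1:n, x3 = n:1, x4 = rep(5, n))
  colnames(x) <- paste0("s", 1:n)
  m <- count_matrix(x, stats::setNames(rep("g", n), colnames(x)))
  expect_warning(net <- correlation_edges(m), "zero-variance")
  key <- edge_key(net$edges)
  expect_true("x1 x2" %in% key)
  r12 <- net$edges$r[net$edges$u == "x1" & net$edges$v == "x2"]
  expect_equal(r12, 1)
  r13 <- net$edges$r[paste(net$edges$u, net$edges$v) %in%
                       c("x1 x3", "x3 x1")]
  expect_equal(r13, -1)              # negative edges are kept, signed
  expect_false("x4" %in% c(net$edges$u, net$edges$v))

  set.seed(42)
  for (i in 1:3) {
    r <- cpm_normalize(random_count_matrix(20, c(A = 4, B = 4), lambda = 20))
    net <- suppressWarnings(correlation_edges(r))
    oracle <- brute_force_edges(
      apply(r$counts, 1, rank) |> t(), method = "pearson")
    expect_setequal(edge_key(net$edges), edge_key(oracle))
  }

  small <- count_matrix(matrix(1:6, 2, 3,
                               dimnames = list(c("a", "b"), paste0("s", 1:3))),
                        stats::setNames(rep("g", 3), paste0("s", 1:3)))
  expect_error(correlation_edges(small), "4 samples")
})

test_that("greedy community detection maximizes modularity on small graphs", {
  # two triangles joined by one edge
  tri2 <- data.frame(u = c("a", "b", "a", "d", "e", "d", "c"),
                     v = c("b", "c", "c", "e", "f", "f", "d"))
  net <- make_network(letters[1:6], tri2)
  com <- greedy_modularity(net)
  expect_equal(length(unique(com$membership)), 2)
  expect_length(unique(com$membership[c("a", "b", "c")]), 1)
  expect_length(unique(com$membership[c("d", "e", "f")]), 1)

  # exhaustive oracle: greedy attains the global maximum here
  parts <- all_partitions(6)
  qs <- vapply(parts, function(p)
    modularity_oracle(tri2, stats::setNames(p, letters[1:6])), 0)
  expect_equal(com$modularity, max(qs), tolerance = 1e-12)

  # a single clique stays one community
  clique <- expand.grid(u = letters[1:4], v = letters[1:4],
                        stringsAsFactors = FALSE)
  clique <- clique[clique$u < clique$v, ]
  one <- greedy_modularity(make_network(letters[1:4], clique))
  expect_equal(length(unique(one$membership)), 1)

  # partition beats the trivial partitions; isolated nodes become singletons
  set.seed(43)
  for (i in 1:3) {
    nodes <- paste0("n", 1:10)
    pairs <- t(utils::combn(nodes, 2))
    pick <- sample(nrow(pairs), 14)
    ed <- data.frame(u = pairs[pick, 1], v = pairs[pick, 2])
    net <- make_network(c(nodes, "iso"), ed)
    com <- greedy_modularity(net)
    expect_equal(sum(com$membership == com$membership[["iso"]]), 1)
    singletons <- stats::setNames(seq_along(net$nodes), net$nodes)
    lumped <- stats::setNames(rep(1, length(net$nodes)), net$nodes)
    expect_gte(com$modularity, modularity_oracle(ed, singletons) - 1e-12)
    expect_gte(com$modularity, modularity_oracle(ed, lumped) - 1e-12)
  }

  empty <- make_network(c("a", "b"), data.frame(u = character(0),
                                                v = character(0)))
  com <- greedy_modularity(empty)
  expect_equal(com$modularity, 0)
  expect_equal(length(unique(com$membership)), 2)
})

test_that("hub scores are the principal eigenvector, normalized to max 1", {
  # star: center 1, leaves 1/sqrt(n-1)
  star <- make_network(c("hub", paste0("l", 1:5)),
                       data.frame(u = "hub", v = paste0("l", 1:5)))
  h <- hub_scores(star)
  expect_equal(unname(h["hub"]), 1)
  expect_equal(unname(h[paste0("l", 1:5)]), rep(1 / sqrt(5), 5),
               tolerance = 1e-9)

  # one edge: symmetric tie at 1; isolated node scores 0
  pair <- make_network(c("u", "v", "w"), data.frame(u = "u", v = "v"))
  h <- hub_scores(pair)
  expect_equal(unname(h[c("u", "v")]), c(1, 1))
  expect_equal(unname(h["w"]), 0)

  # invariant under node relabeling
  set.seed(44)
  nodes <- paste0("n", 1:12)
  pairs <- t(utils::combn(nodes, 2))
  pick <- sample(nrow(pairs), 20)
  ed <- data.frame(u = pairs[pick, 1], v = pairs[pick, 2])
  net <- make_network(nodes, ed)
  h1 <- hub_scores(net)
  relabel <- stats::setNames(paste0("m", sample(12)), nodes)
  ed2 <- data.frame(u = unname(relabel[ed$u]), v = unname(relabel[ed$v]))
  h2 <- hub_scores(make_network(unname(relabel[nodes]), ed2))
  expect_equal(unname(h2[unname(relabel[nodes])]), unname(h1[nodes]),
               tolerance = 1e-9)
})

test_that("within-module z and participation follow their closed forms", {
  # two 3-cliques joined by one edge: equal kappa within each -> z = 0
  tri2 <- data.frame(u = c("a", "b", "a", "d", "e", "d", "c"),
                     v = c("b", "c", "c", "e", "f", "f", "d"))
  net <- make_network(letters[1:6], tri2)
  mem <- stats::setNames(rep(1:2, each = 3), letters[1:6])
  z <- within_module_z(net, mem)
  expect_equal(unname(z), rep(0, 6))

  # a dominant node inside its community has the largest positive z,
  # and z values sum to ~0 where the sd is positive
  star_plus <- data.frame(u = c("h", "h", "h", "h", "a", "x"),
                          v = c("a", "b", "c", "d", "b", "y"))
  net2 <- make_network(c("h", letters[1:4], "x", "y"), star_plus)
  mem2 <- stats::setNames(c(1, 1, 1, 1, 1, 2, 2), c("h", letters[1:4], "x", "y"))
  z2 <- within_module_z(net2, mem2)
  expect_gt(z2[["h"]], 0)
  expect_equal(unname(z2[["h"]]), max(z2[mem2 == 1]))
  expect_equal(sum(z2[mem2 == 1]), 0, tolerance = 1e-12)

  # participation: all internal edges -> 0; even split over m communities
  # -> 1 - 1/m
  p <- participation_coefficient(net, mem)
  expect_equal(unname(p[c("a", "b", "e", "f")]), rep(0, 4))
  for (m_comm in 2:4) {
    sat <- paste0("s", seq_len(2 * m_comm))
    ed <- data.frame(u = "ctr", v = sat)
    netm <- make_network(c("ctr", sat), ed)
    memm <- stats::setNames(c(1, rep(seq_len(m_comm), each = 2) + 1),
                            c("ctr", sat))
    pm <- participation_coefficient(netm, memm)
    expect_equal(unname(pm[["ctr"]]), 1 - 1 / m_comm, tolerance = 1e-12)
  }
})

test_that("role classification applies the documented joint thresholds", {
  z <- c(a = 3.0, b = 0.5, c = 2.5, d = 3.0, e = 0.1)
  p <- c(a = 0.1, b = 0.7, c = 0.62, d = 0.8, e = 0.2)
  roles <- classify_roles(z, p)
  expect_equal(unname(roles["a"]), "module_hub")
  expect_equal(unname(roles["b"]), "connector")
  expect_equal(unname(roles["c"]), "module_hub")   # boundary: >= and <=
  expect_equal(unname(roles["d"]), "network_hub")
  expect_equal(unname(roles["e"]), "peripheral")
})

test_that("top-k subnetworks are induced subgraphs with deterministic ties", {
  set.seed(45)
  r <- cpm_normalize(random_count_matrix(25, c(A = 4, B = 4), lambda = 20))
  net <- suppressWarnings(correlation_edges(r))
  sc <- score_network(net)
  rank_hub <- stats::setNames(sc$nodes$hub_score, sc$nodes$taxon)

  full <- topk_subnetwork(net, rank_hub, k = length(net$nodes))
  expect_setequal(full$nodes, net$nodes)
  expect_equal(nrow(full$edges), nrow(net$edges))

  expect_warning(topk_subnetwork(net, rank_hub, k = 500), "all nodes")

  # identical rankings give identical node sets
  a <- topk_subnetwork(net, rank_hub, k = 10)
  b <- topk_subnetwork(net, rank_hub, k = 10)
  expect_identical(a$nodes, b$nodes)
  expect_equal(overlap_percent(length(intersect(a$nodes, b$nodes)), "union",
                               size_a = 10, size_b = 10), 100)

  # tie-break by node id: constant ranking keeps the lexicographic head
  const <- stats::setNames(rep(1, length(net$nodes)), net$nodes)
  expect_identical(topk_subnetwork(net, const, k = 5)$nodes,
                   sort(net$nodes)[1:5])

  # induced edges only connect selected nodes
  expect_true(all(a$edges$u %in% a$nodes) && all(a$edges$v %in% a$nodes))
})

test_that("score multisets are invariant under node relabeling", {
  set.seed(46)
  r <- cpm_normalize(random_count_matrix(20, c(A = 4, B = 4), lambda = 20))
  net <- suppressWarnings(correlation_edges(r))
  sc1 <- score_network(net)
  perm <- sample(nrow(r$counts))
  r2 <- count_matrix(r$counts[perm, ], stats::setNames(r$groups, r$samples),
                     "CPM")
  sc2 <- score_network(suppressWarnings(correlation_edges(r2)))
  o1 <- sc1$nodes[order(sc1$nodes$taxon), ]
  o2 <- sc2$nodes[order(sc2$nodes$taxon), ]
  expect_equal(o1$hub_score, o2$hub_score, tolerance = 1e-9)
  expect_equal(o1$degree, o2$degree)
  expect_equal(sort(o1$participation), sort(o2$participation),
               tolerance = 1e-9)
})
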