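# Graph construction, Markov clustering, ranking, betweenness.

edges_from <- function(a, b, s) {
  suppressWarnings(edge_table(data.frame(node_a = a, node_b = b, score = s)))
}

test_that("build_graph keeps the score boundary inclusive", {
  e <- edges_from(c("A", "B", "C"), c("B", "C", "D"), c(0.39, 0.40, 0.95))
  g <- build_graph(e, c("A", "B", "C", "D"), threshold = 0.4)
  expect_equal(igraph::ecount(g$graph), 2)
  expect_equal(g$isolated, "A")

  g0 <- build_graph(e, c("A", "B", "C", "D"), threshold = 0)
  expect_equal(igraph::ecount(g0$graph), 3)

  expect_error(build_graph(e, character(0)), "empty")
  expect_warning(gx <- build_graph(e, c("X", "Y")), "isolated")
  expect_equal(igraph::vcount(gx$graph), 2)
  expect_equal(igraph::ecount(gx$graph), 0)
})

test_that("MCL resolves disconnected components and isolated nodes", {
  e <- edges_from(c("A", "B", "C", "X", "Y", "Z"),
                  c("B", "C", "A", "Y", "Z", "X"), rep(1, 6))
  g <- build_graph(e, c("A", "B", "C", "X", "Y", "Z", "LONE"), threshold = 0.4)
  cs <- mcl_cluster(g)
  expect_equal(length(cs$clusters), 3)
  expect_setequal(vapply(cs$clusters, paste, "", collapse = ","),
                  c("A,B,C", "X,Y,Z", "LONE"))
  # partition: disjoint cover
  expect_setequal(unlist(cs$clusters), c("A", "B", "C", "X", "Y", "Z", "LONE"))
  expect_equal(sum(cs$sizes), 7)
  expect_error(mcl_cluster(g, inflation = 1), "inflation")
})

test_that("MCL splits the 12-node barbell at the weak bridge", {
  # two 6-cliques joined by one 0.4 edge; frozen expectation from a
  # 60-digit-precision re-execution of the same iteration: the two
  # bridge endpoints become the attractors and the partition is exactly
  # the two cliques
  lo <- sprintf("L%d", 1:6); hi <- sprintf("R%d", 1:6)
  a <- character(0); b <- character(0)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- c(a, lo[i], hi[i]); b <- c(b, lo[j], hi[j])
  }
  e <- edges_from(c(a, "L6"), c(b, "R1"), c(rep(1, 30), 0.4))
  g <- build_graph(e, c(lo, hi), threshold = 0.4)
  cs <- mcl_cluster(g, inflation = 1.9)
  expect_true(cs$converged)
  expect_equal(length(cs$clusters), 2)
  expect_setequal(vapply(cs$clusters, paste, "", collapse = ","),
                  c(paste(lo, collapse = ","), paste(hi, collapse = ",")))
})

test_that("columns stay stochastic through inflation and pruning", {
  set.seed(10)
  cfg <- sim_config(n_proteins = 60, n_modules = 4, module_size = 15,
                    p_in = 0.9, p_out = 0.05, seed = 10)
  tr <- gen_counts(cfg)$truth
  g <- build_graph(gen_network(cfg, tr), names(tr$module), threshold = 0.4)
  cs <- mcl_cluster(g)
  expect_lt(cs$colsum_dev, 1e-9)
})

test_that("MCL output is a partition and is invariant to relabeling", {
  for (s in 1:3) {
    cfg <- sim_config(n_proteins = 40, n_modules = 3, module_size = 10,
                      p_in = 0.85, p_out = 0.05, seed = s)
    tr <- gen_counts(cfg)$truth
    ed <- gen_network(cfg, tr)
    g <- build_graph(ed, names(tr$module), threshold = 0.4)
    cs <- mcl_cluster(g)
    expect_setequal(unlist(cs$clusters), names(tr$module))
    expect_equal(anyDuplicated(unlist(cs$clusters)), 0)

    # rename every node; the partition must map over unchanged
    nodes <- sort(unique(names(tr$module)))
    newname <- setNames(sprintf("N%03d", rev(seq_along(nodes))), nodes)
    ed2 <- ed
    ed2$node_a <- unname(newname[ed$node_a])
    ed2$node_b <- unname(newname[ed$node_b])
    g2 <- build_graph(ed2, unname(newname[names(tr$module)]), threshold = 0.4)
    cs2 <- mcl_cluster(g2)
    m1 <- cs$membership[nodes]
    m2 <- cs2$membership[unname(newname[nodes])]
    expect_equal(adjusted_rand_index(m1, m2), 1)
  }
})

test_that("cluster ranking breaks ties by weight then smallest member", {
  # components: K4; two triangles with different internal weights; an edge
  e <- edges_from(
    c("A1", "A1", "A1", "A2", "A2", "A3",  "B1", "B1", "B2",
      "C1", "C1", "C2",  "D1"),
    c("A2", "A3", "A4", "A3", "A4", "A4",  "B2", "B3", "B3",
      "C2", "C3", "C3",  "D2"),
    c(rep(1, 6), 0.9, 0.9, 0.9, 0.5, 0.5, 0.5, 1))
  g <- build_graph(e, c(paste0("A", 1:4), paste0("B", 1:3),
                        paste0("C", 1:3), "D1", "D2"), threshold = 0.4)
  cs <- mcl_cluster(g)
  r <- rank_clusters(cs, g, top_k = 8)
  expect_equal(r$size, c(4, 3, 3, 2))
  # heavier triangle (B, 2.7) outranks the lighter one (C, 1.5)
  expect_equal(substr(r$members[2], 1, 1), "B")
  expect_equal(substr(r$members[3], 1, 1), "C")
  r1 <- rank_clusters(cs, g, top_k = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$size, 4)

  # equal sizes, equal weights: lexicographic smallest member, stable
  e2 <- edges_from(c("M1", "K1"), c("M2", "K2"), c(0.8, 0.8))
  g2 <- build_graph(e2, c("M1", "M2", "K1", "K2"), threshold = 0.4)
  cs2 <- mcl_cluster(g2)
  r2 <- rank_clusters(cs2, g2, top_k = 2)
  expect_equal(substr(r2$members, 1, 1), c("K", "M"))
  expect_identical(r2, rank_clusters(cs2, g2, top_k = 2))
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  path3 <- build_graph(edges_from(c("A", "B"), c("B", "C"), c(1, 1)),
                       c("A", "B", "C"), 0.4)
  b <- node_betweenness(path3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  # 4-cycle: for each node, one opposite pair has 2 shortest paths of
  # which 1 passes through it -> raw 0.5, normalized by (3*2)/2 = 3
  cyc <- build_graph(edges_from(c("A", "B", "C", "D"),
                                c("B", "C", "D", "A"), rep(1, 4)),
                     LETTERS[1:4], 0.4)
  expect_equal(unname(node_betweenness(cyc)), rep(0.5 / 3, 4))

  k4 <- build_graph(edges_from(c("A", "A", "A", "B", "B", "C"),
                               c("B", "C", "D", "C", "D", "D"), rep(1, 6)),
                    LETTERS[1:4], 0.4)
  expect_equal(unname(node_betweenness(k4)), rep(0, 4))

  # nodes in components smaller than 3 score zero
  tiny <- build_graph(edges_from("A", "B", 1), c("A", "B", "Z"), 0.4)
  expect_equal(unname(node_betweenness(tiny)), c(0, 0, 0))
})

test_that("adjusted Rand index is 1 on identical and ~0 on random labels", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  set.seed(77)
  a <- sample(1:4, 400, replace = TRUE)
  b <- sample(1:4, 400, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})
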