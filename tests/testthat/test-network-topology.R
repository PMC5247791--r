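test_that("minShortestPathToSet takes the minimum BFS distance to the driver set", {
  net <- netFromEdges(list(c("g", "a"), c("a", "b"), c("b", "d"),
                           c("x", "y")))
  expect_equal(minShortestPathToSet(net, "d", "d"), 0L)
  expect_equal(minShortestPathToSet(net, "b", "d"), 1L)
  expect_equal(minShortestPathToSet(net, "g", "d"), 3L)
  expect_equal(minShortestPathToSet(net, "g", c("d", "a")), 1L)
  expect_true(is.na(minShortestPathToSet(net, "x", "d")))  # unreachable
  expect_error(minShortestPathToSet(net, "zz", "d"), "zz")
})

test_that("msp agrees with a brute-force BFS oracle and is 1-Lipschitz on edges", {
  set.seed(91)
  for (rep in 1:20) {
    nv <- sample(5:10, 1)
    edges <- randomConnectedGraph(nv)
    nms <- paste0("v", seq_len(nv))
    net <- netFromEdges(lapply(seq_len(nrow(edges)), function(k)
      nms[edges[k, ]]), nodes = nms)
    drivers <- nms[sample(nv, sample(1:2, 1))]
    adj <- adjFromEdges(edges, nv)
    dmat <- vapply(match(drivers, nms), function(r) bfsDistOracle(adj, r),
                   integer(nv))
    oracle <- apply(dmat, 1, min)
    got <- minShortestPathToSet(net, nms, drivers)
    expect_equal(got, as.integer(oracle))
    for (k in seq_len(nrow(edges)))
      expect_lte(abs(got[edges[k, 1]] - got[edges[k, 2]]), 1L)
  }
})

test_that("bipartiteBetweenness credits interior vertices of source-target paths", {
  path <- netFromEdges(list(c("s", "v"), c("v", "t")))
  bbc <- bipartiteBetweenness(path, "s", "t")
  expect_equal(bbc[["v"]], 1)
  expect_equal(bbc[["s"]], 0)  # endpoints receive no credit
  expect_equal(bbc[["t"]], 0)
  # vertex off every shortest path scores 0
  net <- netFromEdges(list(c("s", "v"), c("v", "t"), c("s", "u"),
                           c("u", "w")))
  expect_equal(bipartiteBetweenness(net, "s", "t")[["w"]], 0)
  expect_warning(z <- bipartiteBetweenness(net, character(), "t"), "empty")
  expect_true(all(z == 0))
})

test_that("a cut vertex between the two groups attains strictly maximal bbc", {
  # two clusters joined through the single cut vertex D
  net <- netFromEdges(list(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                           c("a2", "D"), c("a3", "D"),
                           c("D", "b2"), c("D", "b3"),
                           c("b1", "b2"), c("b1", "b3"), c("b2", "b3")))
  bbc <- bipartiteBetweenness(net, sources = c("a1", "a2", "a3"),
                              targets = c("b1", "b2", "b3"))
  others <- setdiff(names(bbc), "D")
  expect_true(all(bbc[["D"]] > bbc[others]))
})

test_that("with sources = targets = all vertices bbc doubles standard betweenness", {
  set.seed(92)
  for (rep in 1:10) {
    nv <- sample(6:12, 1)
    edges <- randomConnectedGraph(nv)
    nms <- paste0("v", seq_len(nv))
    net <- netFromEdges(lapply(seq_len(nrow(edges)), function(k)
      nms[edges[k, ]]), nodes = nms)
    bbc <- bipartiteBetweenness(net, nms, nms)
    ref <- igraph::betweenness(asIgraph(net), directed = FALSE)
    expect_equal(unname(bbc[nms]), unname(2 * ref[nms]), tolerance = 1e-10)
  }
})

test_that("bbc matches exhaustive shortest-path enumeration on small graphs", {
  set.seed(93)
  for (rep in 1:30) {
    nv <- sample(4:8, 1)
    edges <- randomConnectedGraph(nv)
    nms <- paste0("v", seq_len(nv))
    net <- netFromEdges(lapply(seq_len(nrow(edges)), function(k)
      nms[edges[k, ]]), nodes = nms)
    src <- sample(nv, sample(1:3, 1))
    tgt <- sample(nv, sample(1:3, 1))
    got <- bipartiteBetweenness(net, nms[src], nms[tgt])
    oracle <- bbcOracle(edges, nv, src, tgt)
    expect_equal(unname(got[nms]), oracle, tolerance = 1e-10)
  }
})

test_that("rankSumTest matches the exhaustive rank statistic", {
  tie <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$U, 4.5)  # |x||y|/2
  expect_equal(tie$p, 1)
  sep <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  shift <- rankSumTest(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(shift$U, sep$U)
  expect_equal(shift$p, sep$p)
  flat <- rankSumTest(rep(2, 4), rep(2, 5))
  expect_equal(flat$p, 1)
})

test_that("permutationTestMeanDiff is seeded and matches exact enumeration", {
  vals <- c(a = 1, b = 2, c = 3, d = 4, e = 10, f = 11, g = 12, h = 13)
  labs <- rep(c("other", "dc"), each = 4)
  p1 <- permutationTestMeanDiff(vals, labs, n_perm = 4000, seed = 7)
  p2 <- permutationTestMeanDiff(vals, labs, n_perm = 4000, seed = 7)
  expect_identical(p1, p2)
  # exact p by enumerating all C(8,4) = 70 assignments
  obs <- mean(vals[labs == "dc"]) - mean(vals[labs == "other"])
  combs <- combn(8, 4)
  stats <- apply(combs, 2, function(ix) mean(vals[ix]) - mean(vals[-ix]))
  exact <- mean(abs(stats) >= abs(obs) - 1e-12)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(p1 - exact), 3 * se + 1 / 4000)
  same <- permutationTestMeanDiff(c(a = 1, b = 1, c = 1, d = 1),
                                  c("dc", "dc", "other", "other"),
                                  n_perm = 200, seed = 1)
  expect_equal(same, 1)
})

test_that("topologyAnnotation assembles per-gene measures and group tests", {
  net <- netFromEdges(list(c("k", "d1"), c("d1", "d2"), c("d2", "p1"),
                           c("k", "o1"), c("o1", "o2"), c("o2", "p2"),
                           c("d1", "o1")))
  res <- topologyAnnotation(net, drivers = "k", dc_genes = c("d1", "d2"),
                            n_perm = 200, seed = 3)
  tab <- res$table
  expect_equal(tab$msp[tab$gene == "k"], 0L)
  expect_true(all(tab$is_peripheral[tab$gene %in% c("p1", "p2")]))
  expect_equal(sort(tab$gene[tab$is_dc]), c("d1", "d2"))
  expect_true(all(c("msp", "bbc") %in% res$stats$measure))
})
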