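test_that("TOM subgraph extraction is the module-member union", {
  ids <- sprintf("P%02d", 1:10)
  tom <- matrix(runif(100, 0.1, 0.9), 10, dimnames = list(ids, ids))
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  lab <- setNames(c(rep(1L, 3), rep(2L, 3), rep(0L, 4)), ids)
  g <- tomSubgraph(tom, lab, c(1, 2))
  expect_equal(length(g$nodes), 6L)
  expect_equal(sum(g$edges & upper.tri(g$edges)), 15L)   # complete graph
  expect_true(all(g$weights[g$edges] >= 0 & g$weights[g$edges] <= 1))
  expect_true(isSymmetric(unname(g$weights[g$nodes, g$nodes])))
  # unassigned proteins stay out even if topologically adjacent
  expect_false(any(ids[7:10] %in% g$nodes))
  expect_error(tomSubgraph(tom, lab, c(1, 9)), "not present")
  expect_error(tomSubgraph(tom, lab, 1), "at least 2")
})

test_that("mean-weight thresholding keeps ties and recounts edges", {
  ids <- c("A", "B", "C")
  w <- matrix(c(1, 0.1, 0.9, 0.1, 1, 0.5, 0.9, 0.5, 1), 3,
              dimnames = list(ids, ids))
  lab <- setNames(c(1L, 1L, 2L), ids)
  g <- thresholdEdges(tomSubgraph(w, lab, 1:2))
  expect_equal(g$threshold, mean(c(0.1, 0.9, 0.5)))
  expect_equal(g$n_edges_kept, 2L)                 # 0.9 and 0.5 >= 0.5
  expect_true(g$edges["A", "C"] && g$edges["B", "C"])
  expect_false(g$edges["A", "B"])
  # all weights equal: nothing is strictly below the mean
  w2 <- matrix(0.4, 3, 3, dimnames = list(ids, ids))
  diag(w2) <- 1
  g2 <- thresholdEdges(tomSubgraph(w2, lab, 1:2))
  expect_equal(g2$n_edges_kept, 3L)
  # random graph: kept count equals an independent recount
  set.seed(60)
  tomr <- matrix(runif(64), 8)
  tomr <- (tomr + t(tomr)) / 2
  diag(tomr) <- 1
  ids8 <- sprintf("N%d", 1:8)
  dimnames(tomr) <- list(ids8, ids8)
  labr <- setNames(rep(c(1L, 2L), each = 4), ids8)
  gr <- thresholdEdges(tomSubgraph(tomr, labr, 1:2))
  ut <- upper.tri(tomr)
  m <- mean(tomr[ut])
  expect_equal(gr$n_edges_kept, sum(tomr[ut] >= m))
})

test_that("subset betweenness solves canonical small graphs", {
  # path A - B - C: all flow through B
  ids <- c("A", "B", "C")
  w <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(w) <- 1
  e <- matrix(FALSE, 3, 3, dimnames = list(ids, ids))
  e["A", "B"] <- e["B", "A"] <- e["B", "C"] <- e["C", "B"] <- TRUE
  g <- structure(list(nodes = ids, weights = w, edges = e,
                      module = setNames(rep(1L, 3), ids),
                      threshold = NA_real_), class = "tomGraph")
  bt <- subsetBetweenness(g, "A", "C", normalized = FALSE)
  expect_equal(unname(bt), c(0, 1, 0))
  # complete graph: direct edges are the unique shortest paths
  e2 <- matrix(TRUE, 3, 3, dimnames = list(ids, ids)); diag(e2) <- FALSE
  g2 <- structure(list(nodes = ids, weights = w, edges = e2,
                       module = setNames(rep(1L, 3), ids),
                       threshold = NA_real_), class = "tomGraph")
  bt2 <- subsetBetweenness(g2, c("A", "B"), "C", normalized = FALSE)
  expect_true(all(bt2 == 0))
  expect_error(subsetBetweenness(g2, character(0), "C"), "non-empty")
  expect_warning(subsetBetweenness(g2, c("A", "B"), c("B", "C")),
                 "removed")
})

test_that("subset betweenness matches exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    g <- randomTomGraph(n, p_edge = 0.55)
    src <- sample(g$nodes, sample(1:2, 1))
    avail <- setdiff(g$nodes, src)
    tgt <- sample(avail, sample(seq_len(min(3, length(avail))), 1))
    for (mode in c("unweighted", "tom_distance")) {
      got <- subsetBetweenness(g, src, tgt, path_mode = mode)
      ref <- bruteSubsetBetweenness(g$edges, g$weights,
                                    match(src, g$nodes),
                                    match(tgt, g$nodes),
                                    weighted = mode == "tom_distance")
      expect_equal(unname(got), ref, tolerance = 1e-9)
    }
  }
})

test_that("all-pairs subset betweenness reduces to classical betweenness", {
  set.seed(62)
  g <- randomTomGraph(7, p_edge = 0.6)
  got <- subsetBetweenness(g, g$nodes, g$nodes, normalized = FALSE)
  # classical (undirected) betweenness counts each unordered pair once
  ref <- bruteSubsetBetweenness(g$edges, g$weights, 1:7, 1:7,
                                normalized = FALSE)
  expect_equal(unname(got), ref, tolerance = 1e-9)
})

test_that("ranking orders by g with kME and id tie-breaks", {
  g <- c(P1 = 0.5, P2 = 0.5, P3 = 0.1, P4 = 0)
  lab <- setNames(c(1L, 1L, 1L, 2L), names(g))
  kme <- c(P1 = 0.6, P2 = 0.9, P3 = 0.2, P4 = 0.5)
  res <- rankBottlenecks(g, lab, 1L, kme = kme)
  expect_equal(res$protein, c("P2", "P1", "P3"))
  expect_equal(res$rank, 1:3)
  expect_false(attr(res, "no_signal"))
  res0 <- rankBottlenecks(c(P1 = 0, P2 = 0, P3 = 0), lab, 1L)
  expect_true(attr(res0, "no_signal"))
  expect_equal(res0$protein, c("P1", "P2", "P3"))   # lexicographic
})

test_that("the planted bottleneck tops its source-module ranking", {
  fx <- smallCohort()
  truth <- fx$truth
  x <- fx$x
  lab <- plantedLabels(truth, rownames(x))
  el <- moduleEigenproteins(x, lab)
  km <- moduleKME(x, el$E)
  bid <- truth@bottleneckId
  targets <- match(names(truth@bottleneckWeights),
                   rownames(truth@groupEffects))
  src <- targets[which.max(km$kme[bid, paste0("M", targets)])]
  lab[bid] <- src
  tom <- tomSimilarity(signedAdjacency(networkCorrelationOf(x), 11))
  graph <- thresholdEdges(tomSubgraph(tom, lab, targets))
  sources <- names(lab)[lab == src]
  g <- subsetBetweenness(graph, sources, setdiff(graph$nodes, sources))
  res <- rankBottlenecks(g, lab, src,
                         kme = setNames(km$kme[, paste0("M", src)],
                                        rownames(km$kme)))
  expect_equal(res$protein[1], bid)
  expect_lt(graph$n_edges_kept, graph$n_edges_total)
  # the planted bridge carries far more flow than any module member
  expect_gt(g[bid], max(g[setdiff(names(g), bid)]))
})

test_that("thresholding order matters (subgraph first, then threshold)", {
  fx <- smallCohort()
  net <- smallNetwork()
  tom <- tomMatrix(net)
  lab <- moduleLabels(net)
  mods <- c(1L, 2L)
  g1 <- thresholdEdges(tomSubgraph(tom, lab, mods))
  # thresholding the full matrix first yields a different edge set
  full_mean <- mean(tom[upper.tri(tom)])
  nodes <- g1$nodes
  kept_global <- tom[nodes, nodes] >= full_mean
  diag(kept_global) <- FALSE
  expect_false(identical(unname(g1$edges), unname(kept_global)))
})
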