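triangleKG <- function() {
  knowledgeGraph(data.frame(id = c("a", "b", "c"),
                            type = rep("gene", 3)),
                 data.frame(source = c("a", "a", "b"),
                            target = c("b", "c", "c")))
}

test_that("nodeMeasures matches closed forms on hand-sized graphs", {
  # isolated node: degree 0, subgraph centrality exp(0) = 1
  iso <- knowledgeGraph(data.frame(id = "a", type = "gene"))
  nm <- nodeMeasures(iso)
  expect_equal(nm$degree, 0L)
  expect_equal(nm$subgraph_centrality, 1, tolerance = 1e-10)
  expect_equal(nm$neighborhood_connectivity, 0)

  # K2: each endpoint has subgraph centrality cosh(1)
  k2 <- knowledgeGraph(data.frame(id = c("a", "b"), type = c("gene", "gene")),
                       data.frame(source = "a", target = "b"))
  expect_equal(nodeMeasures(k2)$subgraph_centrality, rep(cosh(1), 2),
               tolerance = 1e-10)

  # triangle: clustering 1, neighborhood connectivity 2
  tri <- nodeMeasures(triangleKG())
  expect_equal(tri$clustering_coefficient, rep(1, 3))
  expect_equal(tri$neighborhood_connectivity, rep(2, 3))
})

test_that("subgraph centrality agrees with the truncated power-series oracle", {
  seriesSC <- function(g, kmax = 30) {
    a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    acc <- diag(nrow(a))
    p <- diag(nrow(a))
    for (k in seq_len(kmax)) {
      p <- p %*% a
      acc <- acc + p / factorial(k)
    }
    diag(acc)
  }
  for (s in 1:5) {
    gen <- generateBipartiteKG(kgSpec(6, 6, nBlocks = 2, pIn = 0.7,
                                      pOut = 0.2, holdoutFraction = 0,
                                      seed = s))
    expect_equal(nodeMeasures(gen$kg)$subgraph_centrality,
                 unname(seriesSC(asIgraph(gen$kg))), tolerance = 1e-6)
  }
})

test_that("graphMeasures reproduces the published GDKG-scale closed forms", {
  gen <- generateBipartiteKG(kgSpec(149, 150, nBlocks = 1, pIn = 0.11,
                                    pOut = 0, holdoutFraction = 0, seed = 42))
  kg <- gen$kg
  expect_equal(numNodes(kg), 299L)
  gm <- graphMeasures(kg)
  # density and mean neighbor count depend only on |V| and |E|
  expect_equal(gm$density, 2 * numEdges(kg) / (299 * 298))
  expect_equal(gm$average_neighbors, 2 * numEdges(kg) / 299)
})

test_that("spectral gap follows both conventions", {
  k4 <- knowledgeGraph(data.frame(id = letters[1:4], type = rep("gene", 4)),
                       expand.grid(source = letters[1:4],
                                   target = letters[1:4],
                                   stringsAsFactors = FALSE) |>
                         subset(source < target))
  # K4 adjacency eigenvalues are 3 and -1: gap 2
  expect_equal(graphMeasures(k4, "adjacency")$spectral_gap, 2,
               tolerance = 1e-10)
  # disconnected graph: transition-convention gap is 0
  disc <- knowledgeGraph(data.frame(id = letters[1:4], type = rep("gene", 4)),
                         data.frame(source = c("a", "c"),
                                    target = c("b", "d")))
  expect_equal(graphMeasures(disc, "transition")$spectral_gap, 0)
  # connected non-bipartite graph mixes: positive transition gap
  expect_gt(graphMeasures(triangleKG(), "transition")$spectral_gap, 0)
})

test_that("cycle measures: girth, trace diagnostic, diameter", {
  c4 <- knowledgeGraph(data.frame(id = letters[1:4], type = rep("gene", 4)),
                       data.frame(source = c("a", "b", "c", "d"),
                                  target = c("b", "c", "d", "a")))
  gm <- graphMeasures(c4)
  expect_equal(gm$girth, 4)
  expect_equal(gm$diameter, 2)
  expect_equal(gm$density, 2 / 3)
  # the trace variant is 2 for any graph with an edge
  expect_equal(traceGirth(c4), 2)
  tree <- knowledgeGraph(data.frame(id = letters[1:3], type = rep("gene", 3)),
                         data.frame(source = c("a", "b"),
                                    target = c("b", "c")))
  expect_equal(graphMeasures(tree)$girth, Inf)
})

test_that("density and average neighbors strictly increase with an added edge", {
  nodes <- data.frame(id = letters[1:5], type = rep("gene", 5))
  g1 <- knowledgeGraph(nodes, data.frame(source = c("a", "b"),
                                         target = c("b", "c")))
  g2 <- knowledgeGraph(nodes, data.frame(source = c("a", "b", "d"),
                                         target = c("b", "c", "e")))
  m1 <- graphMeasures(g1); m2 <- graphMeasures(g2)
  expect_gt(m2$density, m1$density)
  expect_gt(m2$average_neighbors, m1$average_neighbors)
  expect_true(m1$density >= 0 && m1$density <= 1)
})

test_that("paScore is the degree product and is symmetric", {
  kg <- pathKG()   # degrees: g1=1, g2=2, d1=2, d2=1
  expect_equal(paScore(kg, rbind(c("g1", "d2"))), 1)
  expect_equal(paScore(kg, rbind(c("g2", "d1"))), 4)
  expect_error(paScore(kg, rbind(c("g1", "zz"))), "unknown node")

  # published degrees: ATF3 = 17, PTEN = 36 -> PA = 612
  tab <- exampleGeneMeasures()
  pa <- tab$degree[tab$gene == "ATF3"] * tab$degree[tab$gene == "PTEN"]
  expect_equal(pa, 612)

  # symmetry on random pairs of a 12-node graph, against the closed form
  gen <- generateBipartiteKG(kgSpec(6, 6, nBlocks = 2, pIn = 0.6, pOut = 0.1,
                                    holdoutFraction = 0, seed = 4))
  nd <- kgNodes(gen$kg)
  set.seed(1)
  pairs <- cbind(sample(nd$id, 100, TRUE), sample(nd$id, 100, TRUE))
  deg <- igraph::degree(asIgraph(gen$kg))
  expect_equal(paScore(gen$kg, pairs),
               unname(deg[pairs[, 1]] * deg[pairs[, 2]]))
  expect_equal(paScore(gen$kg, pairs), paScore(gen$kg, pairs[, 2:1]))
})
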