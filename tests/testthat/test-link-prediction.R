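test_that("splitEdges yields disjoint, layer-respecting labeled pairs", {
  gen <- generateBipartiteKG(kgSpec(40, 40, nBlocks = 2, pIn = 0.5,
                                    pOut = 0.05, holdoutFraction = 0.1,
                                    seed = 2))
  kg <- gen$kg
  m <- numEdges(kg)
  sp <- splitEdges(kg, 0.1, 1, seed = 5, forbidden = gen$heldOut)
  expect_equal(nrow(sp@testPositives), round(0.1 * m))
  expect_equal(numEdges(sp@trainGraph), m - round(0.1 * m))

  pkey <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  obs <- pkey(as.matrix(kgEdges(kg)))
  held <- pkey(gen$heldOut)
  for (negs in list(sp@negatives, sp@trainNegatives)) {
    expect_length(intersect(pkey(negs), obs), 0)
    expect_length(intersect(pkey(negs), held), 0)
    # layer respected: one gene, one disease per pair
    types <- stats::setNames(kgNodes(kg)$type, kgNodes(kg)$id)
    expect_true(all(types[negs[, 1]] != types[negs[, 2]]))
  }
  expect_length(intersect(pkey(sp@negatives), pkey(sp@trainNegatives)), 0)
  # deterministic per seed
  sp2 <- splitEdges(kg, 0.1, 1, seed = 5, forbidden = gen$heldOut)
  expect_identical(sp@negatives, sp2@negatives)
  expect_identical(sp@testPositives, sp2@testPositives)

  # complete bipartite graph has no non-edges to sample
  full <- knowledgeGraph(
    data.frame(id = c("g1", "g2", "d1"), type = c("gene", "gene", "disease")),
    data.frame(source = c("g1", "g2"), target = c("d1", "d1")),
    layer = "GDKG")
  expect_error(splitEdges(full, 0.5, 1, seed = 1), "non-edges")
})

test_that("labeledPairs reproduces the published pair bookkeeping", {
  # 1,195 positives at ratio 0.84 gives 1,004 negatives, 2,199 pairs
  expect_equal(ceiling(0.84 * 1195), 1004)
  gen <- generateBipartiteKG(kgSpec(60, 60, nBlocks = 3, pIn = 0.4,
                                    pOut = 0.02, holdoutFraction = 0,
                                    seed = 3))
  lp <- labeledPairs(gen$kg, negativeRatio = 0.84, seed = 1)
  m <- numEdges(gen$kg)
  expect_equal(nrow(lp$pairs), m + ceiling(0.84 * m))
  expect_equal(sum(lp$labels), m)
})

test_that("biased walks follow the transition rules", {
  # single edge: walks alternate between the two endpoints
  k2 <- knowledgeGraph(data.frame(id = c("u", "v"),
                                  type = c("gene", "disease")),
                       data.frame(source = "u", target = "v"),
                       layer = "GDKG")
  walks <- generateWalks(k2, walkConfig(numWalks = 2, walkLength = 5,
                                        seed = 1))
  for (w in walks) expect_true(all(w == c(w[1], setdiff(c("u", "v"), w[1]))
                                   [c(1, 2, 1, 2, 1)]))

  # p = q = 1 on a star: next-node frequencies uniform over the leaves
  star <- knowledgeGraph(data.frame(id = c("hub", sprintf("l%d", 1:5)),
                                    type = c("gene", rep("disease", 5))),
                         data.frame(source = "hub",
                                    target = sprintf("l%d", 1:5)),
                         layer = "GDKG")
  walks <- generateWalks(star, walkConfig(numWalks = 400, walkLength = 11,
                                          seed = 2))
  hubWalks <- Filter(function(w) w[1] == "hub", walks)
  nxt <- table(vapply(hubWalks, `[`, character(1), 2))
  n <- length(hubWalks)
  expect_true(all(abs(nxt / n - 0.2) < 3 * sqrt(0.2 * 0.8 / n)))

  # fixed seed: identical corpus; isolated starts skipped
  expect_identical(generateWalks(star, walkConfig(seed = 9)),
                   generateWalks(star, walkConfig(seed = 9)))
  iso <- knowledgeGraph(data.frame(id = c("a", "b", "c"),
                                   type = c("gene", "disease", "gene")),
                        data.frame(source = "a", target = "b"),
                        layer = "GDKG")
  expect_message(w <- generateWalks(iso, walkConfig(numWalks = 1, seed = 1)),
                 "isolated")
  expect_false("c" %in% unlist(w))
})

test_that("deterministic embeddings separate communities and are reproducible", {
  # two disconnected near-cliques: within-clique cosine beats cross-clique
  seps <- vapply(1:5, function(s) {
    gen <- generateBipartiteKG(kgSpec(20, 20, nBlocks = 2, pIn = 0.8,
                                      pOut = 0, holdoutFraction = 0,
                                      seed = s))
    walks <- generateWalks(gen$kg, walkConfig(numWalks = 5, walkLength = 20,
                                              seed = s))
    emb <- suppressMessages(learnEmbeddings(walks, dim = 16, window = 5))
    V <- embeddingMatrix(emb)
    V <- V / sqrt(rowSums(V^2))
    ids <- rownames(V)
    num <- as.integer(substring(ids, 2))
    blk <- ifelse(substr(ids, 1, 1) == "g",
                  gen$blocks$source[num], gen$blocks$target[num])
    S <- V %*% t(V)
    same <- outer(blk, blk, `==`) & upper.tri(S)
    diff <- outer(blk, blk, `!=`) & upper.tri(S)
    mean(S[same]) - mean(S[diff])
  }, numeric(1))
  expect_true(all(seps > 0))

  # bit-identical on a fixed corpus; requested dimension always honored
  gen <- generateBipartiteKG(kgSpec(15, 15, nBlocks = 3, pIn = 0.6,
                                    pOut = 0.05, holdoutFraction = 0,
                                    seed = 4))
  walks <- generateWalks(gen$kg, walkConfig(numWalks = 3, walkLength = 15,
                                            seed = 4))
  e1 <- suppressMessages(learnEmbeddings(walks, dim = 100, window = 5))
  e2 <- suppressMessages(learnEmbeddings(walks, dim = 100, window = 5))
  expect_identical(embeddingMatrix(e1), embeddingMatrix(e2))
  expect_equal(ncol(embeddingMatrix(e1)), 100)
  expect_identical(e1@mode, "ppmi")
  # rank-deficient corpora are zero-padded
  expect_gt(e1@meta$padded, 0)
})

test_that("edgeFeatures operators are symmetric with the advertised algebra", {
  v <- matrix(c(1, 0, 0, 1, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("e1", "e2", "w"), NULL))
  emb <- methods::new("NodeEmbeddings", vectors = v, mode = "ppmi",
                      meta = list())
  # identical vectors under l1: zero vector
  expect_equal(as.numeric(edgeFeatures(emb, rbind(c("w", "w")), "l1")),
               c(0, 0))
  # hadamard of disjoint-support basis vectors: zero vector
  expect_equal(as.numeric(edgeFeatures(emb, rbind(c("e1", "e2")), "hadamard")),
               c(0, 0))
  for (op in c("hadamard", "average", "l1", "l2"))
    expect_equal(edgeFeatures(emb, rbind(c("e1", "w")), op),
                 edgeFeatures(emb, rbind(c("w", "e1")), op))
  expect_error(edgeFeatures(emb, rbind(c("e1", "zz"))), "zz")
})

test_that("classifier predictors learn planted structure; labels permuted kill it", {
  fx <- smallLinkFixture(seed = 7)
  ev <- evalPairsOf(fx$split, fx$emb)
  for (m in c("random_forest", "gradient_boosting")) {
    pred <- suppressMessages(
      trainPredictor(fx$split, fx$emb,
                     predictorConfig(m, rfEstimators = 300, gbRounds = 80,
                                     seed = 1)))
    auc <- rocAuroc(ev$labels, predictProbability(pred, ev$pairs))$auroc
    expect_gt(auc, 0.75)
  }
  # no-signal null: shuffled labels give AUROC near 0.5
  tp <- as.matrix(kgEdges(fx$split@trainGraph))
  tn <- fx$split@trainNegatives
  pairs <- rbind(tp, tn)
  have <- rownames(embeddingMatrix(fx$emb))
  ok <- pairs[, 1] %in% have & pairs[, 2] %in% have
  X <- edgeFeatures(fx$emb, pairs[ok, ])
  y <- c(rep(1L, nrow(tp)), rep(0L, nrow(tn)))[ok]
  Xe <- edgeFeatures(fx$emb, ev$pairs)
  nulls <- vapply(1:3, function(ps) {
    set.seed(ps)
    cfg <- predictorConfig("random_forest", rfEstimators = 300, seed = ps)
    model <- RepurposeKG:::.fitModel(X, sample(y), cfg)
    rocAuroc(ev$labels, RepurposeKG:::.predictModel(model, Xe, cfg))$auroc
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.12)
})

test_that("the PA predictor favors hubs on degree-heterogeneous graphs", {
  aucs <- vapply(1:3, function(s) {
    out <- generateHubBipartiteKG(80, 80, meanEdgeProb = 0.08,
                                  exponent = 0.9, holdoutFraction = 0.1,
                                  seed = s)
    sp <- splitEdges(out$kg, 0.15, 1, seed = s, forbidden = out$heldOut)
    pred <- trainPredictor(sp, cfg = predictorConfig("pa"))
    ev <- evalPairsOf(sp)
    rocAuroc(ev$labels, predictProbability(pred, ev$pairs))$auroc
  }, numeric(1))
  expect_gt(mean(aucs), 0.6)
  # PA probabilities are the rescaled degree products
  out <- generateHubBipartiteKG(30, 30, seed = 5)
  sp <- splitEdges(out$kg, 0.2, 1, seed = 5)
  pred <- trainPredictor(sp, cfg = predictorConfig("pa"))
  ev <- evalPairsOf(sp)
  pa <- paScore(sp@trainGraph, ev$pairs)
  expect_equal(predictProbability(pred, ev$pairs),
               pmin(pa / pred@model$scale, 1))
})

test_that("predictNewLinks reports sorted, thresholded, bipartite candidates", {
  fx <- smallLinkFixture(seed = 9)
  pred <- suppressMessages(
    trainPredictor(fx$split, fx$emb,
                   predictorConfig("random_forest", rfEstimators = 300,
                                   seed = 2)))
  full <- fx$gen$kg
  out3 <- suppressMessages(predictNewLinks(pred, full, threshold = 0.3))
  out6 <- suppressMessages(predictNewLinks(pred, full, threshold = 0.6))
  # monotone in the threshold, sorted by probability
  expect_gte(nrow(out3), nrow(out6))
  expect_true(all(diff(out3$probability) <= 0))
  expect_true(all(out3$probability >= 0.3))
  expect_true(all(out3$is_new_edge))
  # no reported pair is an observed edge; the layer is respected
  ek <- paste(kgEdges(full)$source, kgEdges(full)$target)
  expect_length(intersect(paste(out3$source, out3$target), ek), 0)
  types <- stats::setNames(kgNodes(full)$type, kgNodes(full)$id)
  expect_true(all(types[out3$source] != types[out3$target]))
  # existing edges come along with label 1
  expect_true(all(attr(out3, "existing")$label == 1))
  expect_error(predictNewLinks(pred, full, threshold = 1.5), "threshold")
})

test_that("held-out positives dominate the top of a dense-block ranking", {
  precs <- vapply(1:3, function(s) {
    gen <- generateBipartiteKG(kgSpec(60, 60, nBlocks = 4, pIn = 0.95,
                                      pOut = 0.01, holdoutFraction = 0.2,
                                      seed = s))
    sp <- splitEdges(gen$kg, 0.1, 1, seed = s, forbidden = gen$heldOut)
    walks <- generateWalks(sp@trainGraph, walkConfig(numWalks = 5,
                                                     walkLength = 40,
                                                     seed = s))
    emb <- suppressMessages(learnEmbeddings(walks, dim = 32, window = 5))
    pred <- suppressMessages(
      trainPredictor(sp, emb, predictorConfig("random_forest",
                                              rfEstimators = 300, seed = s)))
    ranked <- suppressMessages(predictNewLinks(pred, gen$kg,
                                               threshold = 1e-6))
    top <- head(ranked, 20)
    heldKey <- paste(gen$heldOut[, 1], gen$heldOut[, 2])
    mean(paste(top$source, top$target) %in% heldKey)
  }, numeric(1))
  expect_gte(mean(precs), 0.7)
})

test_that("fixed seeds give end-to-end deterministic candidate tables", {
  runOnce <- function() {
    gen <- generateBipartiteKG(kgSpec(40, 40, nBlocks = 2, pIn = 0.5,
                                      pOut = 0.03, holdoutFraction = 0.1,
                                      seed = 21))
    sp <- splitEdges(gen$kg, 0.1, 1, seed = 21, forbidden = gen$heldOut)
    walks <- generateWalks(sp@trainGraph,
                           walkConfig(numWalks = 4, walkLength = 30,
                                      seed = 21))
    emb <- suppressMessages(learnEmbeddings(walks, dim = 24, window = 5))
    pred <- suppressMessages(
      trainPredictor(sp, emb, predictorConfig("gradient_boosting",
                                              gbRounds = 60, seed = 21)))
    suppressMessages(predictNewLinks(pred, gen$kg, threshold = 0.5))
  }
  expect_identical(runOnce(), runOnce())
})
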