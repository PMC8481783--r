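test_that("ciTest behaves like a calibrated Fisher-z test", {
  # perfect dependence: duplicated variable drives p to zero
  set.seed(1)
  v <- rnorm(100)
  dup <- rbind(a = v, b = v + rnorm(100, sd = 1e-8), c = rnorm(100))
  expect_lt(ciTest("a", "b", character(), dup)$pvalue, 1e-12)

  # null p-values are approximately uniform (marginal independence)
  reps <- 500
  pv <- vapply(seq_len(reps), function(s) {
    set.seed(s)
    x <- matrix(rnorm(2 * 200), 2, 200, dimnames = list(c("a", "b"), NULL))
    ciTest("a", "b", character(), x)$pvalue
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)

  # conditional independence along a chain holds at close to nominal level
  rej <- vapply(seq_len(500), function(s) {
    d <- chainData(300, seed = s)
    ciTest("x", "z", "y", d)$pvalue < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)

  # guards: degrees of freedom, argument sanity, constant input
  tiny <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(ciTest("a", "b", "c", tiny), "insufficient samples")
  expect_error(ciTest("a", "a", character(), tiny), "differ")
  flat <- rbind(a = rep(1, 50), b = rnorm(50))
  expect_warning(out <- ciTest("a", "b", character(), flat), "constant")
  expect_equal(out$pvalue, 1)
})

test_that("iamb recovers chain and collider blankets at large n", {
  # chain x -> y -> z: MB(y) = {x, z} in at least 90% of replicates
  hitsY <- vapply(1:20, function(s) {
    d <- chainData(2000, seed = s)
    identical(iamb("y", d, alpha = 0.01)$members, c("x", "z"))
  }, logical(1))
  expect_gte(mean(hitsY), 0.9)

  # collider x -> z <- y: spouse y enters MB(x) through conditioning on z
  hitsX <- vapply(1:20, function(s) {
    d <- colliderData(2000, seed = s)
    setequal(iamb("x", d, alpha = 0.01)$members, c("y", "z"))
  }, logical(1))
  expect_gte(mean(hitsX), 0.8)

  # single-gene matrix: empty blanket
  one <- matrix(rnorm(10), 1, 10, dimnames = list("g1", NULL))
  expect_length(iamb("g1", one)$members, 0)
})

test_that("iamb degrades to marginal screening when samples are too few", {
  x <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(letters[1:5], NULL))
  expect_warning(mb <- iamb("a", x, alpha = 0.05), "marginal")
  expect_s3_class(mb, "MarkovBlanket")
})

test_that("buildGRN controls false edges and recovers chain skeletons", {
  # independent genes: OR-rule edge density bounded by twice the test level
  alpha <- 0.05
  dens <- vapply(1:40, function(s) {
    set.seed(s)
    x <- matrix(rnorm(8 * 150), 8, 150,
                dimnames = list(sprintf("g%d", 1:8), NULL))
    grn <- buildGRN(x, alpha = alpha)
    igraph::ecount(asIgraph(grn)) / choose(8, 2)
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lte(mean(dens), 2 * alpha + 3 * se)

  # 10-gene chain: skeleton F1 >= 0.9 with the OR rule
  f1s <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 2000
    x <- matrix(0, 10, n, dimnames = list(sprintf("g%02d", 1:10), NULL))
    x[1, ] <- rnorm(n)
    for (i in 2:10) x[i, ] <- 0.8 * x[i - 1, ] + rnorm(n)
    grn <- buildGRN(x, alpha = 0.01)
    got <- igraph::as_edgelist(asIgraph(grn))
    gotKey <- paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2]))
    trueKey <- paste(sprintf("g%02d", 1:9), sprintf("g%02d", 2:10))
    tp <- length(intersect(gotKey, trueKey))
    prec <- tp / max(length(gotKey), 1)
    rec <- tp / length(trueKey)
    if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(mean(f1s), 0.9)

  # sample order is irrelevant to the inferred network
  set.seed(99)
  x <- matrix(rnorm(5 * 300), 5, 300, dimnames = list(letters[1:5], NULL))
  g1 <- buildGRN(x, alpha = 0.05)
  g2 <- buildGRN(x[, sample(300)], alpha = 0.05)
  expect_identical(igraph::as_edgelist(asIgraph(g1)),
                   igraph::as_edgelist(asIgraph(g2)))
})

test_that("alpha monotonicity: stricter levels do not add false edges", {
  counts <- sapply(1:30, function(s) {
    set.seed(s)
    x <- matrix(rnorm(6 * 120), 6, 120,
                dimnames = list(sprintf("g%d", 1:6), NULL))
    vapply(c(0.1, 0.05, 0.01), function(a)
      igraph::ecount(asIgraph(buildGRN(x, alpha = a))), numeric(1))
  })
  m <- rowMeans(counts)
  se <- apply(counts, 1, sd) / sqrt(ncol(counts))
  expect_lte(m[2], m[1] + 3 * (se[1] + se[2]))
  expect_lte(m[3], m[2] + 3 * (se[2] + se[3]))
})

test_that("rankRegulators orders by degree with lexicographic ties", {
  star <- knowledgeGraph(data.frame(id = c("hub", letters[1:4]),
                                    type = rep("gene", 5)),
                         data.frame(source = "hub", target = letters[1:4]))
  grn <- methods::new("GeneRegulatoryNetwork", graph = asIgraph(star),
                      blankets = list(), alpha = 0.05, rule = "OR")
  expect_identical(rankRegulators(grn, 1), "hub")
  # all-isolated nodes: pure lexicographic order
  iso <- igraph::make_empty_graph(4, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = c("d", "b", "a", "c"))
  grn2 <- methods::new("GeneRegulatoryNetwork", graph = iso,
                       blankets = list(), alpha = 0.05, rule = "OR")
  expect_identical(rankRegulators(grn2, 4), c("a", "b", "c", "d"))
  expect_error(rankRegulators(grn2, 5), "topK")
  # insertion order of nodes never changes the ranking
  perm <- igraph::permute(asIgraph(star), c(3, 1, 2, 5, 4))
  grn3 <- methods::new("GeneRegulatoryNetwork", graph = perm,
                       blankets = list(), alpha = 0.05, rule = "OR")
  expect_identical(rankRegulators(grn3, 5), rankRegulators(grn, 5))
})
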