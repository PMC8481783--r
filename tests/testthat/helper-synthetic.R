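# Shared fixture builders. Everything is generated in code at test time.

# Tiny deterministic typed graph: two genes, two diseases, a path
pathKG <- function() {
  knowledgeGraph(
    nodes = data.frame(id = c("g1", "g2", "d1", "d2"),
                       type = c("gene", "gene", "disease", "disease")),
    edges = data.frame(source = c("g1", "g2", "g2"),
                       target = c("d1", "d1", "d2")),
    layer = "GDKG")
}

# Structure with explicit edges, for Markov-blanket oracles
structureFromEdges <- function(ids, edges) {
  dag <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), ncol = 2)
  colnames(dag) <- c("parent", "child")
  structure(list(geneIds = ids, dag = dag, order = ids,
                 spec = grnSpec(length(ids), maxParents = max(1L, length(ids) - 1L),
                                edgeProb = 0.5)),
            class = "TrueStructure")
}

# Brute-force Markov blanket oracle: unions parents/children/spouses read
# directly off the edge list
bruteForceMB <- function(structure) {
  ids <- structure$geneIds
  dag <- structure$dag
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (g in ids) {
    members <- character()
    for (i in seq_len(nrow(dag))) {
      if (dag[i, "child"] == g) members <- c(members, dag[i, "parent"])
      if (dag[i, "parent"] == g) {
        members <- c(members, dag[i, "child"])
        ch <- dag[i, "child"]
        for (j in seq_len(nrow(dag)))
          if (dag[j, "child"] == ch) members <- c(members, dag[j, "parent"])
      }
    }
    out[[g]] <- sort(setdiff(unique(members), g))
  }
  out
}

# Linear-Gaussian chain x -> y -> z with unit coefficients
chainData <- function(n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- x + rnorm(n)
  z <- y + rnorm(n)
  rbind(x = x, y = y, z = z)
}

# Collider x -> z <- y with independent x, y
colliderData <- function(n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rnorm(n)
  z <- x + y + rnorm(n)
  rbind(x = x, y = y, z = z)
}

# Small planted-block KG plus derived split/embeddings for predictor tests
smallLinkFixture <- function(seed = 1, nSide = 60, pIn = 0.5, pOut = 0.02) {
  gen <- generateBipartiteKG(kgSpec(nSide, nSide, nBlocks = 3, pIn = pIn,
                                    pOut = pOut, holdoutFraction = 0.1,
                                    seed = seed))
  split <- splitEdges(gen$kg, 0.15, 1, seed = seed, forbidden = gen$heldOut)
  walks <- generateWalks(split@trainGraph,
                         walkConfig(numWalks = 5, walkLength = 40, seed = seed))
  emb <- suppressMessages(learnEmbeddings(walks, dim = 32, window = 5))
  list(gen = gen, split = split, emb = emb)
}

evalPairsOf <- function(split, emb = NULL) {
  ev <- rbind(split@testPositives, split@negatives)
  lab <- c(rep(1L, nrow(split@testPositives)), rep(0L, nrow(split@negatives)))
  if (!is.null(emb)) {
    have <- rownames(embeddingMatrix(emb))
    ok <- ev[, 1] %in% have & ev[, 2] %in% have
    ev <- ev[ok, , drop = FALSE]
    lab <- lab[ok]
  }
  list(pairs = ev, labels = lab)
}
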