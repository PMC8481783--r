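## Cross-layer pair enumeration helpers. Pairs are encoded as
## (i-1)*|B| + j over the two bipartite sides, so uniform sampling without
## replacement over non-edges is exact and deterministic per seed.

.bipartiteSides <- function(kg) {
  nd <- kgNodes(kg)
  want <- switch(kg@layer,
                 GDKG = c("gene", "disease"),
                 DDKG = c("disease", "drug"),
                 generic = NULL)
  if (is.null(want)) {
    tys <- sort(unique(nd$type))
    if (length(tys) != 2L)
      stop("generic graph must have exactly two node types for cross-layer sampling")
    want <- tys
  }
  list(a = sort(nd$id[nd$type == want[1L]]),
       b = sort(nd$id[nd$type == want[2L]]))
}

.pairKeys <- function(pairs, sides) {
  ia <- match(pairs[, 1L], sides$a)
  ib <- match(pairs[, 2L], sides$b)
  flip <- is.na(ia)
  ia[flip] <- match(pairs[flip, 2L], sides$a)
  ib[flip] <- match(pairs[flip, 1L], sides$b)
  if (anyNA(ia) || anyNA(ib)) stop("pair outside the bipartite layer")
  (ia - 1) * length(sides$b) + ib
}

.keysToPairs <- function(keys, sides) {
  ia <- ((keys - 1) %/% length(sides$b)) + 1
  ib <- ((keys - 1) %% length(sides$b)) + 1
  cbind(source = sides$a[ia], target = sides$b[ib])
}

.sampleNegatives <- function(kg, n, seed, forbidden = NULL) {
  sides <- .bipartiteSides(kg)
  total <- length(sides$a) * length(sides$b)
  edges <- as.matrix(kgEdges(kg))
  used <- if (nrow(edges)) .pairKeys(edges, sides) else numeric()
  if (!is.null(forbidden) && nrow(forbidden))
    used <- c(used, .pairKeys(as.matrix(forbidden), sides))
  avail <- setdiff(seq_len(total), used)
  if (n > length(avail))
    stop(sprintf("requested %d negatives but only %d cross-layer non-edges exist",
                 n, length(avail)))
  set.seed(seed)
  .keysToPairs(sort(sample(avail, n)), sides)
}

#' Split knowledge-graph edges into train and held-out labeled pairs
#'
#' Uniformly withholds `testFraction` of the edges as test positives and
#' samples cross-layer non-edges as negatives without replacement:
#' `ceiling(negativeRatio * n)` for the evaluation set and the same ratio
#' again, disjointly, for classifier training. Negatives never coincide
#' with an observed edge or with any pair listed in `forbidden` (e.g.
#' known held-out true links of a synthetic graph). Deterministic per
#' seed.
#'
#' @param kg a [KnowledgeGraph-class] with a bipartite layer.
#' @param testFraction fraction of edges withheld, in (0, 1).
#' @param negativeRatio negatives sampled per positive (> 0). The default
#'   0.84 matches the labeled-pair composition used throughout the
#'   package (1,195 positives + 1,004 negatives = 2,199 pairs).
#' @param seed integer seed.
#' @param forbidden optional two-column matrix of pairs negatives must
#'   avoid.
#' @return an [EdgeSplit-class].
#' @export
splitEdges <- function(kg, testFraction = 0.1, negativeRatio = 0.84,
                       seed = 1L, forbidden = NULL) {
  stopifnot(methods::is(kg, "KnowledgeGraph"),
            testFraction > 0, testFraction < 1, negativeRatio > 0)
  edges <- as.matrix(kgEdges(kg))
  m <- nrow(edges)
  if (m < 2L) stop("too few edges to split")
  set.seed(seed)
  nTest <- max(1L, round(testFraction * m))
  testIdx <- sort(sample.int(m, nTest))
  test <- edges[testIdx, , drop = FALSE]
  gTrain <- igraph::delete_edges(
    kg@graph, igraph::get_edge_ids(kg@graph, as.vector(t(test))))
  trainKG <- .kgFromIgraph(gTrain, kg@layer)
  nNegTest <- ceiling(negativeRatio * nTest)
  nNegTrain <- ceiling(negativeRatio * (m - nTest))
  negAll <- .sampleNegatives(kg, nNegTest + nNegTrain, seed = seed + 1L,
                             forbidden = forbidden)
  pick <- sample.int(nrow(negAll), nNegTest)
  methods::new("EdgeSplit", trainGraph = trainKG,
               testPositives = test,
               negatives = negAll[sort(pick), , drop = FALSE],
               trainNegatives = negAll[-sort(pick), , drop = FALSE],
               seed = as.integer(seed))
}

#' Full labeled-pair set of a knowledge graph
#'
#' All observed edges (label 1) plus `ceiling(negativeRatio * |E|)`
#' sampled cross-layer non-edges (label 0); the composition used for
#' k-fold cross-validation of the link classifiers.
#'
#' @inheritParams splitEdges
#' @return list with `pairs` (character matrix) and `labels` (0/1).
#' @export
labeledPairs <- function(kg, negativeRatio = 0.84, seed = 1L,
                         forbidden = NULL) {
  edges <- as.matrix(kgEdges(kg))
  m <- nrow(edges)
  if (m < 1L) stop("graph has no edges")
  neg <- .sampleNegatives(kg, ceiling(negativeRatio * m), seed = seed,
                          forbidden = forbidden)
  list(pairs = rbind(edges, neg),
       labels = c(rep(1L, m), rep(0L, nrow(neg))))
}

#' Configuration of a link predictor
#'
#' Bundles the method and its hyperparameters. Defaults follow the
#' settings used for the knowledge-graph link predictors: random forest
#' of depth 15 with 500 trees, gradient boosting with learning rate 0.2,
#' and an MLP with two named presets -- `"deep"` (10 hidden layers of 100
#' relu units, adam) and `"shallow"` (one hidden layer of 300 tanh units,
#' lbfgs).
#'
#' @param method `"pa"`, `"random_forest"`, `"gradient_boosting"` or
#'   `"mlp"`.
#' @param rfDepth,rfEstimators random-forest depth cap and tree count.
#' @param gbLearningRate,gbRounds,gbDepth gradient-boosting step size,
#'   boosting rounds and tree depth.
#' @param mlpPreset `"deep"` or `"shallow"`; set `mlpHidden`,
#'   `mlpActivation`, `mlpSolver` to override.
#' @param mlpHidden integer vector of hidden sizes (overrides preset).
#' @param mlpActivation `"relu"` or `"tanh"`.
#' @param mlpSolver `"adam"` or `"lbfgs"`.
#' @param mlpMaxIter optimizer iteration cap.
#' @param mlpDecay L2 weight decay of the MLP.
#' @param seed integer seed.
#' @return object of class `PredictorConfig`.
#' @export
predictorConfig <- function(method = c("random_forest", "gradient_boosting",
                                       "mlp", "pa"),
                            rfDepth = 15L, rfEstimators = 500L,
                            gbLearningRate = 0.2, gbRounds = 150L,
                            gbDepth = 6L,
                            mlpPreset = c("deep", "shallow"),
                            mlpHidden = NULL, mlpActivation = NULL,
                            mlpSolver = NULL, mlpMaxIter = 300L,
                            mlpDecay = 0.1, seed = 1L) {
  method <- match.arg(method)
  mlpPreset <- match.arg(mlpPreset)
  preset <- if (mlpPreset == "deep")
    list(hidden = rep(100L, 10L), activation = "relu", solver = "adam")
  else list(hidden = 300L, activation = "tanh", solver = "lbfgs")
  stopifnot(rfDepth >= 1L, rfEstimators >= 1L, gbLearningRate > 0,
            gbRounds >= 1L, gbDepth >= 1L, mlpMaxIter >= 1L, mlpDecay >= 0)
  structure(list(method = method, rfDepth = as.integer(rfDepth),
                 rfEstimators = as.integer(rfEstimators),
                 gbLearningRate = gbLearningRate,
                 gbRounds = as.integer(gbRounds),
                 gbDepth = as.integer(gbDepth),
                 mlpPreset = mlpPreset,
                 mlpHidden = if (is.null(mlpHidden)) preset$hidden
                 else as.integer(mlpHidden),
                 mlpActivation = if (is.null(mlpActivation)) preset$activation
                 else mlpActivation,
                 mlpSolver = if (is.null(mlpSolver)) preset$solver
                 else mlpSolver,
                 mlpMaxIter = as.integer(mlpMaxIter),
                 mlpDecay = mlpDecay,
                 seed = as.integer(seed)),
            class = "PredictorConfig")
}

## Shared classifier backends (also used by k-fold CV).
.fitModel <- function(X, y, cfg) {
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  switch(cfg$method,
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      num.trees = cfg$rfEstimators, max.depth = cfg$rfDepth,
      probability = TRUE, seed = cfg$seed, num.threads = 1L),
    gradient_boosting = xgboost::xgboost(
      x = as.matrix(X), y = factor(y, levels = c(0, 1)),
      objective = "binary:logistic", nrounds = cfg$gbRounds,
      learning_rate = cfg$gbLearningRate, max_depth = cfg$gbDepth,
      nthreads = 1L, seed = cfg$seed, verbosity = 0L),
    mlp = fitMLP(X, y, hidden = cfg$mlpHidden,
                 activation = cfg$mlpActivation, solver = cfg$mlpSolver,
                 maxIter = cfg$mlpMaxIter, decay = cfg$mlpDecay,
                 seed = cfg$seed),
    stop("no feature-based backend for method ", cfg$method))
}

.predictModel <- function(model, X, cfg) {
  switch(cfg$method,
    random_forest = {
      pr <- stats::predict(model, data = as.data.frame(X),
                           num.threads = 1L)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosting = as.numeric(stats::predict(model, as.matrix(X),
                                                  type = "response")),
    mlp = predictMLP(model, X))
}

#' Train a link predictor on an edge split
#'
#' Classifier methods are trained on the training-graph edges (label 1)
#' plus the split's training negatives (label 0), featurized with
#' [edgeFeatures()]. The `"pa"` method ignores embeddings: it scores a
#' pair by the degree product on the training graph, rescaled to \[0, 1\]
#' by the maximum PA score over the training pairs.
#'
#' @param split an [EdgeSplit-class].
#' @param embeddings a [NodeEmbeddings-class] learned on the training
#'   graph (not needed for `"pa"`).
#' @param cfg a [predictorConfig()].
#' @param operator edge-feature operator (default hadamard).
#' @return a [LinkPredictor-class].
#' @export
trainPredictor <- function(split, embeddings = NULL,
                           cfg = predictorConfig(),
                           operator = "hadamard") {
  stopifnot(methods::is(split, "EdgeSplit"), inherits(cfg, "PredictorConfig"))
  trainPos <- as.matrix(kgEdges(split@trainGraph))
  trainNeg <- split@trainNegatives
  pairs <- rbind(trainPos, trainNeg)
  y <- c(rep(1L, nrow(trainPos)), rep(0L, nrow(trainNeg)))
  if (cfg$method == "pa") {
    sc <- paScore(split@trainGraph, pairs)
    scale <- max(sc, 1)
    return(methods::new("LinkPredictor", method = "pa",
                        model = list(graph = split@trainGraph, scale = scale),
                        embeddings = NULL, operator = operator,
                        meta = list(cfg = cfg, nTrain = length(y))))
  }
  stopifnot(methods::is(embeddings, "NodeEmbeddings"))
  have <- rownames(embeddings@vectors)
  ok <- pairs[, 1L] %in% have & pairs[, 2L] %in% have
  if (any(!ok))
    message(sum(!ok), " training pair(s) dropped: endpoint without embedding")
  X <- edgeFeatures(embeddings, pairs[ok, , drop = FALSE], operator)
  model <- .fitModel(X, y[ok], cfg)
  methods::new("LinkPredictor", method = cfg$method, model = model,
               embeddings = embeddings, operator = operator,
               meta = list(cfg = cfg, nTrain = sum(ok)))
}

setMethod("predictProbability", "LinkPredictor", function(object, pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  if (object@method == "pa") {
    sc <- paScore(object@model$graph, pairs)
    return(pmin(sc / object@model$scale, 1))
  }
  X <- edgeFeatures(object@embeddings, pairs, object@operator)
  .predictModel(object@model, X, object@meta$cfg)
})

#' Score unobserved cross-layer pairs and report candidate links
#'
#' Scores every cross-layer non-edge of `kg` with the predictor, keeps
#' pairs with probability at or above `threshold` (sorted by decreasing
#' probability, ties broken by ids) and flags them `is_new_edge = TRUE`.
#' The observed edges are scored too and attached as the `"existing"`
#' attribute with label 1. Pairs with an endpoint lacking an embedding
#' are skipped with a message.
#'
#' @param predictor a [LinkPredictor-class].
#' @param kg the full observed [KnowledgeGraph-class].
#' @param threshold reporting threshold in (0, 1).
#' @return data.frame `source`, `target`, `probability`,
#'   `predicted_label` (1 iff probability >= 0.5), `is_new_edge`.
#' @export
predictNewLinks <- function(predictor, kg, threshold = 0.8) {
  stopifnot(methods::is(predictor, "LinkPredictor"),
            methods::is(kg, "KnowledgeGraph"),
            threshold > 0, threshold < 1)
  sides <- .bipartiteSides(kg)
  edges <- as.matrix(kgEdges(kg))
  used <- if (nrow(edges)) .pairKeys(edges, sides) else numeric()
  cand <- .keysToPairs(setdiff(seq_len(length(sides$a) * length(sides$b)),
                               used), sides)
  if (predictor@method != "pa") {
    have <- rownames(predictor@embeddings@vectors)
    ok <- cand[, 1L] %in% have & cand[, 2L] %in% have
    if (any(!ok))
      message(sum(!ok), " candidate pair(s) skipped: endpoint without embedding")
    cand <- cand[ok, , drop = FALSE]
  }
  out <- data.frame(source = character(), target = character(),
                    probability = numeric(), predicted_label = integer(),
                    is_new_edge = logical())
  if (nrow(cand)) {
    pr <- predictProbability(predictor, cand)
    keep <- pr >= threshold
    out <- data.frame(source = cand[keep, 1L], target = cand[keep, 2L],
                      probability = pr[keep],
                      predicted_label = as.integer(pr[keep] >= 0.5),
                      is_new_edge = TRUE, row.names = NULL)
    out <- out[order(-out$probability, out$source, out$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(edges)) {
    okE <- if (predictor@method == "pa") rep(TRUE, nrow(edges))
    else edges[, 1L] %in% rownames(predictor@embeddings@vectors) &
      edges[, 2L] %in% rownames(predictor@embeddings@vectors)
    ex <- data.frame(source = edges[okE, 1L], target = edges[okE, 2L],
                     probability = if (any(okE))
                       predictProbability(predictor, edges[okE, , drop = FALSE])
                     else numeric(),
                     label = 1L, row.names = NULL)
    attr(out, "existing") <- ex
  }
  out
}
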