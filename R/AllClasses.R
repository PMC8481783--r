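#' @import methods
#' @importFrom stats cor pnorm rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

.NODE_TYPES <- c("gene", "disease", "drug")
.KG_LAYERS <- c("generic", "GDKG", "DDKG")

#' KnowledgeGraph: a typed, simple, undirected graph
#'
#' Container for the gene-disease (GDKG) and disease-drug (DDKG) knowledge
#' graphs and for generic typed graphs. Wraps an [igraph::igraph] object
#' whose vertices carry a `name` and a `type` attribute
#' (`"gene"`, `"disease"` or `"drug"`).
#'
#' The graph is always simple (no self-loops, no duplicate edges). For the
#' `"GDKG"` layer every edge must join a gene to a disease; for `"DDKG"`
#' every edge must join a disease to a drug. The `"generic"` layer imposes
#' no bipartite constraint.
#'
#' @slot graph an undirected [igraph::igraph] with `name` and `type`
#'   vertex attributes.
#' @slot layer one of `"generic"`, `"GDKG"`, `"DDKG"`.
#'
#' @seealso [knowledgeGraph()], [buildGDKG()], [buildDDKG()]
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph", slots = c(graph = "ANY", layer = "character"))

setValidity("KnowledgeGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops or multi-edges)")
  if (length(object@layer) != 1L || !object@layer %in% .KG_LAYERS)
    return(sprintf("'layer' must be one of %s", paste(.KG_LAYERS, collapse = ", ")))
  nm <- igraph::vertex_attr(g, "name")
  ty <- igraph::vertex_attr(g, "type")
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("every vertex needs a non-empty 'name'")
  if (anyDuplicated(tolower(nm)))
    return("vertex names must be unique (case-insensitively)")
  if (is.null(ty) || !all(ty %in% .NODE_TYPES))
    return("every vertex needs a 'type' in {gene, disease, drug}")
  if (object@layer != "generic" && igraph::ecount(g) > 0L) {
    want <- if (object@layer == "GDKG") c("gene", "disease") else c("disease", "drug")
    el <- igraph::as_edgelist(g, names = TRUE)
    tmap <- stats::setNames(ty, nm)
    et <- cbind(tmap[el[, 1L]], tmap[el[, 2L]])
    ok <- (et[, 1L] == want[1L] & et[, 2L] == want[2L]) |
      (et[, 1L] == want[2L] & et[, 2L] == want[1L])
    if (!all(ok))
      return(sprintf("layer %s requires every edge to join a %s to a %s",
                     object@layer, want[1L], want[2L]))
  }
  TRUE
})

#' GeneRegulatoryNetwork: Markov-blanket-derived gene network
#'
#' Undirected skeleton assembled from per-gene Markov blankets, with the
#' degree-based regulatory-activity score used to select key regulators.
#'
#' @slot graph undirected [igraph::igraph] over the gene ids.
#' @slot blankets named list; one [iamb()] result per gene.
#' @slot alpha significance level used by the conditional-independence
#'   tests.
#' @slot rule symmetry rule that turned blankets into edges
#'   (`"OR"` or `"AND"`).
#'
#' @seealso [buildGRN()], [rankRegulators()]
#' @exportClass GeneRegulatoryNetwork
setClass("GeneRegulatoryNetwork",
         slots = c(graph = "ANY", blankets = "list",
                   alpha = "numeric", rule = "character"))

setValidity("GeneRegulatoryNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (igraph::any_loop(g)) return("no self-loops allowed")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (!object@rule %in% c("OR", "AND")) return("rule must be 'OR' or 'AND'")
  TRUE
})

#' NodeEmbeddings: per-node random-walk feature vectors
#'
#' @slot vectors numeric matrix, one row per embedded node (rownames are
#'   node ids), `dim` columns.
#' @slot mode embedding algorithm, currently `"ppmi"` (deterministic
#'   positive-PMI co-occurrence factorization).
#' @slot meta list of run metadata (window, walk configuration, rank
#'   padding).
#'
#' @seealso [learnEmbeddings()], [edgeFeatures()]
#' @exportClass NodeEmbeddings
setClass("NodeEmbeddings",
         slots = c(vectors = "matrix", mode = "character", meta = "list"))

setValidity("NodeEmbeddings", function(object) {
  v <- object@vectors
  if (!is.numeric(v)) return("'vectors' must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("'vectors' needs unique rownames (node ids)")
  if (anyNA(v)) return("embeddings contain NA")
  TRUE
})

#' EdgeSplit: train graph plus held-out labeled pairs
#'
#' Result of [splitEdges()]. The training graph keeps all nodes but drops
#' the test positives; negatives are cross-layer non-edges sampled
#' disjointly for training and evaluation.
#'
#' @slot trainGraph [KnowledgeGraph-class] with test edges removed.
#' @slot testPositives character matrix (n x 2) of withheld true edges.
#' @slot negatives character matrix (n x 2) of evaluation non-edges.
#' @slot trainNegatives character matrix of non-edges reserved for
#'   classifier training (disjoint from `negatives`).
#' @slot seed integer seed that produced the split.
#'
#' @exportClass EdgeSplit
setClass("EdgeSplit",
         slots = c(trainGraph = "KnowledgeGraph", testPositives = "matrix",
                   negatives = "matrix", trainNegatives = "matrix",
                   seed = "integer"))

#' LinkPredictor: a fitted link-prediction model
#'
#' @slot method one of `"pa"`, `"random_forest"`, `"gradient_boosting"`,
#'   `"mlp"`.
#' @slot model the fitted model object (degree table for `"pa"`).
#' @slot embeddings [NodeEmbeddings-class] used to featurize pairs
#'   (ignored by `"pa"`).
#' @slot operator edge-feature operator (`"hadamard"`, `"average"`,
#'   `"l1"`, `"l2"`).
#' @slot meta list: configuration, training sizes, PA scale.
#'
#' @seealso [trainPredictor()], [predictProbability()], [predictNewLinks()]
#' @exportClass LinkPredictor
setClass("LinkPredictor",
         slots = c(method = "character", model = "ANY",
                   embeddings = "ANY", operator = "character",
                   meta = "list"))
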