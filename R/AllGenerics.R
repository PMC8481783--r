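#' Accessors for knowledge graphs and derived objects
#'
#' `kgNodes()` returns the node table (`id`, `type`), `kgEdges()` the edge
#' table (`source`, `target`), `numNodes()`/`numEdges()` the counts, and
#' `asIgraph()` the underlying [igraph::igraph].
#'
#' @param x a [KnowledgeGraph-class] or [GeneRegulatoryNetwork-class].
#' @return `kgNodes`/`kgEdges` return data.frames; `numNodes`/`numEdges`
#'   integers; `asIgraph` an igraph object.
#' @examples
#' kg <- knowledgeGraph(
#'   nodes = data.frame(id = c("g1", "d1"), type = c("gene", "disease")),
#'   edges = data.frame(source = "g1", target = "d1"), layer = "GDKG")
#' kgNodes(kg)
#' numEdges(kg)
#' @aliases kgNodes kgEdges numNodes numEdges asIgraph
#' @name kg-accessors
NULL

#' @rdname kg-accessors
#' @export
setGeneric("kgNodes", function(x) standardGeneric("kgNodes"))

#' @rdname kg-accessors
#' @export
setGeneric("kgEdges", function(x) standardGeneric("kgEdges"))

#' @rdname kg-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname kg-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname kg-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Regulatory activity scores of a gene regulatory network
#'
#' Activity is operationalized as GRN degree: the number of inferred
#' regulatory partners of each gene.
#'
#' @param x a [GeneRegulatoryNetwork-class].
#' @return named numeric vector of degrees.
#' @export
setGeneric("regulatoryActivity", function(x) standardGeneric("regulatoryActivity"))

#' Markov blankets stored in a gene regulatory network
#'
#' @param x a [GeneRegulatoryNetwork-class].
#' @return named list of [iamb()] results.
#' @export
setGeneric("markovBlankets", function(x) standardGeneric("markovBlankets"))

#' Embedding matrix accessor
#'
#' @param x a [NodeEmbeddings-class].
#' @return numeric matrix (nodes x dim) with node ids as rownames.
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' Score node pairs with a fitted link predictor
#'
#' @param object a [LinkPredictor-class].
#' @param pairs two-column character matrix or data.frame of node pairs.
#' @return numeric vector of link probabilities in \[0, 1\].
#' @export
setGeneric("predictProbability",
           function(object, pairs) standardGeneric("predictProbability"))

#' @describeIn kg-accessors node table of a KnowledgeGraph
setMethod("kgNodes", "KnowledgeGraph", function(x) {
  data.frame(id = igraph::vertex_attr(x@graph, "name"),
             type = igraph::vertex_attr(x@graph, "type"),
             stringsAsFactors = FALSE)
})

#' @describeIn kg-accessors edge table of a KnowledgeGraph
setMethod("kgEdges", "KnowledgeGraph", function(x) {
  el <- igraph::as_edgelist(x@graph, names = TRUE)
  data.frame(source = as.character(el[, 1L]), target = as.character(el[, 2L]),
             stringsAsFactors = FALSE)
})

#' @describeIn kg-accessors number of nodes
setMethod("numNodes", "KnowledgeGraph", function(x) igraph::vcount(x@graph))

#' @describeIn kg-accessors number of edges
setMethod("numEdges", "KnowledgeGraph", function(x) igraph::ecount(x@graph))

#' @describeIn kg-accessors underlying igraph of a KnowledgeGraph
setMethod("asIgraph", "KnowledgeGraph", function(x) x@graph)

#' @describeIn kg-accessors underlying igraph of a GeneRegulatoryNetwork
setMethod("asIgraph", "GeneRegulatoryNetwork", function(x) x@graph)

setMethod("regulatoryActivity", "GeneRegulatoryNetwork", function(x) {
  deg <- igraph::degree(x@graph)
  stats::setNames(as.numeric(deg), igraph::vertex_attr(x@graph, "name"))
})

setMethod("markovBlankets", "GeneRegulatoryNetwork", function(x) x@blankets)

setMethod("embeddingMatrix", "NodeEmbeddings", function(x) x@vectors)

setMethod("show", "KnowledgeGraph", function(object) {
  ty <- table(igraph::vertex_attr(object@graph, "type"))
  cat(sprintf("KnowledgeGraph [%s]: %d nodes, %d edges\n", object@layer,
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  cat("  node types:", paste(sprintf("%s=%d", names(ty), ty), collapse = ", "),
      "\n")
  invisible(object)
})

setMethod("show", "GeneRegulatoryNetwork", function(object) {
  cat(sprintf(
    "GeneRegulatoryNetwork: %d genes, %d edges (IAMB, alpha=%g, %s rule)\n",
    igraph::vcount(object@graph), igraph::ecount(object@graph),
    object@alpha, object@rule))
  invisible(object)
})

setMethod("show", "NodeEmbeddings", function(object) {
  cat(sprintf("NodeEmbeddings [%s]: %d nodes x %d dims\n", object@mode,
              nrow(object@vectors), ncol(object@vectors)))
  invisible(object)
})

setMethod("show", "EdgeSplit", function(object) {
  cat(sprintf(
    "EdgeSplit: train %d edges | %d test positives, %d negatives (seed %d)\n",
    numEdges(object@trainGraph), nrow(object@testPositives),
    nrow(object@negatives), object@seed))
  invisible(object)
})

setMethod("show", "LinkPredictor", function(object) {
  cat(sprintf("LinkPredictor: method=%s, operator=%s\n",
              object@method, object@operator))
  invisible(object)
})
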