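.nodeCompanion <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.csv")
}

#' Read and write knowledge graphs
#'
#' Lossless serialization of a [KnowledgeGraph-class] in three plain-text
#' formats:
#' \describe{
#'   \item{`edgelist`}{edge CSV with columns `source,target` plus a
#'     companion node CSV (`<path>_nodes.csv`) with columns `id,type`.}
#'   \item{`adjacency`}{symmetric 0/1 CSV with node ids as row and column
#'     headers, plus the same companion node CSV carrying the types.}
#'   \item{`graphml`}{GraphML with a `type` node attribute
#'     (Cytoscape-compatible), written through igraph.}
#' }
#' The bipartite invariant of the layer is re-validated on load; malformed
#' edge rows raise an error naming the offending row.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param path file path; for `edgelist`/`adjacency` the node companion
#'   file sits next to it.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @param layer layer to assign on read (`readKG` only).
#' @return `writeKG` returns `path` invisibly; `readKG` returns a
#'   [KnowledgeGraph-class].
#' @export
writeKG <- function(kg, path, format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  stopifnot(methods::is(kg, "KnowledgeGraph"))
  if (format == "edgelist") {
    write.csv(kgEdges(kg), path, row.names = FALSE, quote = TRUE)
    write.csv(kgNodes(kg), .nodeCompanion(path), row.names = FALSE,
              quote = TRUE)
  } else if (format == "adjacency") {
    a <- as.matrix(igraph::as_adjacency_matrix(kg@graph, sparse = FALSE))
    storage.mode(a) <- "integer"
    write.csv(a, path, row.names = TRUE, quote = TRUE)
    write.csv(kgNodes(kg), .nodeCompanion(path), row.names = FALSE,
              quote = TRUE)
  } else {
    igraph::write_graph(kg@graph, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeKG
#' @export
readKG <- function(path, format = c("edgelist", "adjacency", "graphml"),
                   layer = c("generic", "GDKG", "DDKG")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                        type = igraph::vertex_attr(g, "type"))
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(source = el[, 1L], target = el[, 2L])
    return(knowledgeGraph(nodes, edges, layer = layer))
  }
  nodes <- read.csv(.nodeCompanion(path), stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(nodes)))
    stop("node file needs columns id, type: ", .nodeCompanion(path))
  if (format == "edgelist") {
    edges <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(edges)))
      stop("edge file needs columns source, target: ", path)
    bad <- which(is.na(edges$source) | is.na(edges$target) |
                   trimws(edges$source) == "" | trimws(edges$target) == "")
    if (length(bad))
      stop("malformed edge row(s) at line(s): ",
           paste(head(bad + 1L, 5L), collapse = ", "))
  } else {
    a <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
    if (nrow(a) != ncol(a) || !isTRUE(all.equal(a, t(a), check.attributes = FALSE)))
      stop("adjacency CSV must be square and symmetric: ", path)
    idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
    edges <- data.frame(source = rownames(a)[idx[, 1L]],
                        target = colnames(a)[idx[, 2L]])
  }
  knowledgeGraph(nodes, edges, layer = layer)
}
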