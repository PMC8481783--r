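#' Node-level network measures
#'
#' Computes, for every node of a knowledge graph: degree, neighborhood
#' connectivity (mean degree over the node's neighbors, 0 for isolated
#' nodes), subgraph centrality (the node's diagonal entry of the matrix
#' exponential of the adjacency matrix, i.e. the factorially weighted sum
#' of closed walks through the node; >= 1 always, since the length-0 walk
#' contributes 1), and the local clustering coefficient (0 for nodes with
#' fewer than two neighbors; identically 0 on bipartite layers).
#'
#' @param kg a [KnowledgeGraph-class] (or igraph) -- simple, undirected.
#' @return data.frame with columns `id`, `type`, `degree`,
#'   `neighborhood_connectivity`, `subgraph_centrality`,
#'   `clustering_coefficient`.
#' @export
nodeMeasures <- function(kg) {
  g <- if (methods::is(kg, "KnowledgeGraph")) kg@graph else kg
  stopifnot(igraph::is_igraph(g))
  deg <- igraph::degree(g)
  nn <- igraph::knn(g)$knn        # mean neighbor degree; NaN for isolated
  nn[is.nan(nn)] <- 0
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  es <- eigen(a, symmetric = TRUE)
  sc <- as.vector((es$vectors^2) %*% exp(es$values))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(id = igraph::vertex_attr(g, "name"),
             type = if (!is.null(igraph::vertex_attr(g, "type")))
               igraph::vertex_attr(g, "type") else NA_character_,
             degree = as.integer(deg),
             neighborhood_connectivity = as.numeric(nn),
             subgraph_centrality = sc,
             clustering_coefficient = as.numeric(cc),
             row.names = NULL)
}

#' Graph-level network measures
#'
#' Density is `2|E| / (|V| (|V|-1))` and the average number of neighbors
#' `2|E| / |V|` (closed forms for simple undirected graphs). The spectral
#' gap comes in two conventions: `"adjacency"` (default) is
#' `|lambda_1| - |lambda_2|` of the adjacency spectrum ordered by
#' magnitude; `"transition"` is `1 - |lambda_2|` of the random-walk
#' transition matrix, which is 0 for disconnected or bipartite graphs
#' (the walk does not converge). Diameter is the longest shortest path
#' within the largest connected component; girth is the length of the
#' shortest cycle (`Inf` for forests).
#'
#' @param kg a [KnowledgeGraph-class] or igraph with at least one node.
#' @param gapConvention `"adjacency"` or `"transition"`.
#' @return list of class `GraphMeasureRecord`: `density`,
#'   `average_neighbors`, `spectral_gap`, `gap_convention`, `diameter`,
#'   `girth`, `n_nodes`, `n_edges`.
#' @export
graphMeasures <- function(kg, gapConvention = c("adjacency", "transition")) {
  gapConvention <- match.arg(gapConvention)
  g <- if (methods::is(kg, "KnowledgeGraph")) kg@graph else kg
  stopifnot(igraph::is_igraph(g))
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv < 1L) stop("graph has no nodes")
  density <- if (nv > 1L) 2 * ne / (nv * (nv - 1)) else NA_real_
  avg <- 2 * ne / nv
  gap <- if (gapConvention == "adjacency") {
    ev <- abs(eigen(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)),
                    symmetric = TRUE, only.values = TRUE)$values)
    ev <- sort(ev, decreasing = TRUE)
    if (nv == 1L) 0 else ev[1L] - ev[2L]
  } else {
    if (!igraph::is_connected(g) || any(igraph::degree(g) == 0L)) 0 else {
      ## symmetric normalization D^-1/2 A D^-1/2 shares the transition spectrum
      d <- igraph::degree(g)
      a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
      s <- diag(1 / sqrt(d)) %*% a %*% diag(1 / sqrt(d))
      ev <- sort(abs(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
                 decreasing = TRUE)
      if (nv == 1L) 0 else max(0, 1 - ev[2L])
    }
  }
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  diam <- if (igraph::vcount(sub) > 1L) igraph::diameter(sub) else 0
  gir <- suppressWarnings(igraph::girth(g)$girth)
  if (is.null(gir) || length(gir) == 0L || gir == 0) gir <- Inf
  structure(list(density = density, average_neighbors = avg,
                 spectral_gap = gap, gap_convention = gapConvention,
                 diameter = diam, girth = as.numeric(gir),
                 n_nodes = nv, n_edges = ne),
            class = "GraphMeasureRecord")
}

#' Trace-based cycle diagnostic
#'
#' The smallest walk length `r >= 1` with `Trace(A^r) > 0`. Because every
#' edge already yields a closed walk of length 2, this equals 2 for any
#' graph with at least one edge (and 1 only with self-loops); it is kept
#' as a named diagnostic, distinct from the standard shortest-cycle girth
#' reported by [graphMeasures()].
#'
#' @param kg a [KnowledgeGraph-class] or igraph.
#' @param maxLen maximum walk length examined.
#' @return integer walk length, or `Inf` if no closed walk up to
#'   `maxLen`.
#' @export
traceGirth <- function(kg, maxLen = 12L) {
  g <- if (methods::is(kg, "KnowledgeGraph")) kg@graph else kg
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  p <- diag(nrow(a))
  for (r in seq_len(maxLen)) {
    p <- p %*% a
    if (sum(diag(p)) > 0) return(r)
  }
  Inf
}

#' Preferential-attachment link score
#'
#' `PA(u, v) = |Gamma(u)| * |Gamma(v)|`, the product of the endpoint
#' degrees on the (training) graph. Pairs touching an isolated node score
#' 0.
#'
#' @param kg a [KnowledgeGraph-class] or igraph.
#' @param pairs two-column character matrix or data.frame of node pairs;
#'   unknown ids raise an error.
#' @return numeric vector of PA scores, one per pair.
#' @export
paScore <- function(kg, pairs) {
  g <- if (methods::is(kg, "KnowledgeGraph")) kg@graph else kg
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  deg <- igraph::degree(g)
  nm <- igraph::vertex_attr(g, "name")
  unknown <- setdiff(unique(c(pairs)), nm)
  if (length(unknown))
    stop("unknown node id(s): ", paste(head(unknown, 5L), collapse = ", "))
  d <- stats::setNames(as.numeric(deg), nm)
  as.numeric(d[pairs[, 1L]] * d[pairs[, 2L]])
}

#' @export
print.GraphMeasureRecord <- function(x, ...) {
  cat(sprintf(
    "Graph measures (%d nodes, %d edges)\n  density            %.4g\n  average neighbors  %.4g\n  spectral gap (%s) %.4g\n  diameter           %s\n  girth              %s\n",
    x$n_nodes, x$n_edges, x$density, x$average_neighbors, x$gap_convention,
    x$spectral_gap, format(x$diameter), format(x$girth)))
  invisible(x)
}
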