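#' Specification for a planted-block bipartite knowledge graph
#'
#' Source and target nodes are assigned to blocks round-robin; a
#' source-target pair is edged with probability `pIn` when the endpoints
#' share a block and `pOut` otherwise. A fraction of the realized edges is
#' withheld as ground-truth missing links for link-prediction benchmarks.
#'
#' @param nSource,nTarget node counts for the two sides.
#' @param nBlocks number of planted blocks.
#' @param pIn,pOut within- and cross-block edge probabilities,
#'   `0 <= pOut < pIn <= 1`.
#' @param holdoutFraction fraction of realized edges withheld, in
#'   (0, 0.5\]; use `0` to keep every edge observed.
#' @param sourceType,targetType node types (`"gene"`, `"disease"`,
#'   `"drug"`); gene/disease gives a GDKG layer, disease/drug a DDKG.
#' @param seed integer seed.
#' @return an object of class `SyntheticKGSpec` (a validated list).
#' @seealso [generateBipartiteKG()], [generateHubBipartiteKG()]
#' @export
kgSpec <- function(nSource, nTarget, nBlocks = 4L, pIn = 0.2, pOut = 0.01,
                   holdoutFraction = 0.1, sourceType = "gene",
                   targetType = "disease", seed = 1L) {
  stopifnot(nSource >= 1L, nTarget >= 1L, nBlocks >= 1L,
            nBlocks <= min(nSource, nTarget))
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  if (holdoutFraction < 0 || holdoutFraction > 0.5)
    stop("holdoutFraction must lie in [0, 0.5]")
  stopifnot(sourceType %in% .NODE_TYPES, targetType %in% .NODE_TYPES,
            sourceType != targetType)
  structure(list(nSource = as.integer(nSource), nTarget = as.integer(nTarget),
                 nBlocks = as.integer(nBlocks), pIn = pIn, pOut = pOut,
                 holdoutFraction = holdoutFraction, sourceType = sourceType,
                 targetType = targetType, seed = as.integer(seed)),
            class = "SyntheticKGSpec")
}

.sideIds <- function(type, n) {
  prefix <- c(gene = "g", disease = "d", drug = "x")[[type]]
  sprintf("%s%03d", prefix, seq_len(n))
}

.layerFor <- function(sourceType, targetType) {
  ty <- sort(c(sourceType, targetType))
  if (identical(ty, c("disease", "gene"))) "GDKG"
  else if (identical(ty, c("disease", "drug"))) "DDKG"
  else "generic"
}

.finishBipartiteKG <- function(spec, prob, seed) {
  set.seed(seed)
  src <- .sideIds(spec$sourceType, spec$nSource)
  tgt <- .sideIds(spec$targetType, spec$nTarget)
  hit <- which(matrix(runif(length(prob)), nrow(prob)) < prob, arr.ind = TRUE)
  nE <- nrow(hit)
  nHold <- round(spec$holdoutFraction * nE)
  holdIdx <- if (nHold > 0L) sample.int(nE, nHold) else integer()
  mkEdges <- function(rows) {
    if (length(rows) == 0L)
      return(matrix(character(), ncol = 2L,
                    dimnames = list(NULL, c("source", "target"))))
    cbind(source = src[hit[rows, 1L]], target = tgt[hit[rows, 2L]])
  }
  obs <- mkEdges(setdiff(seq_len(nE), holdIdx))
  held <- mkEdges(holdIdx)
  if (nrow(obs) == 0L)
    stop("no observed edges after holdout; increase pIn or graph size")
  nodes <- data.frame(
    id = c(src, tgt),
    type = c(rep(spec$sourceType, spec$nSource),
             rep(spec$targetType, spec$nTarget)))
  kg <- knowledgeGraph(nodes, as.data.frame(obs),
                       layer = .layerFor(spec$sourceType, spec$targetType))
  list(kg = kg, heldOut = held,
       blocks = list(source = ((seq_len(spec$nSource) - 1L) %% spec$nBlocks) + 1L,
                     target = ((seq_len(spec$nTarget) - 1L) %% spec$nBlocks) + 1L))
}

#' Generate a planted-block bipartite knowledge graph
#'
#' @param spec a [kgSpec()].
#' @return list with `kg` (the observed [KnowledgeGraph-class]), `heldOut`
#'   (character matrix of withheld true edges, disjoint from the observed
#'   edges) and `blocks` (block assignment of each side). Deterministic
#'   per seed.
#' @export
generateBipartiteKG <- function(spec) {
  stopifnot(inherits(spec, "SyntheticKGSpec"))
  bs <- ((seq_len(spec$nSource) - 1L) %% spec$nBlocks) + 1L
  bt <- ((seq_len(spec$nTarget) - 1L) %% spec$nBlocks) + 1L
  prob <- ifelse(outer(bs, bt, `==`), spec$pIn, spec$pOut)
  .finishBipartiteKG(spec, prob, spec$seed)
}

#' Generate a degree-heterogeneous bipartite knowledge graph
#'
#' Hub-dominated variant for benchmarking the preferential-attachment
#' scorer: node weights follow a power law (`w_i` proportional to
#' `i^-exponent`) and the edge probability of a pair is proportional to
#' the product of its endpoint weights, scaled to a chosen mean. Withheld
#' edges are a uniform sample of the realized edges and are therefore
#' concentrated on hubs.
#'
#' @param nSource,nTarget node counts.
#' @param meanEdgeProb average pair probability after scaling.
#' @param exponent power-law exponent of the weight sequence (> 0).
#' @param holdoutFraction fraction of realized edges withheld.
#' @param sourceType,targetType node types as in [kgSpec()].
#' @param seed integer seed.
#' @return same shape as [generateBipartiteKG()] (without `blocks`).
#' @export
generateHubBipartiteKG <- function(nSource, nTarget, meanEdgeProb = 0.08,
                                   exponent = 0.9, holdoutFraction = 0.1,
                                   sourceType = "gene", targetType = "disease",
                                   seed = 1L) {
  stopifnot(exponent > 0, meanEdgeProb > 0, meanEdgeProb < 1)
  spec <- kgSpec(nSource, nTarget, nBlocks = 1L, pIn = 1, pOut = 0,
                 holdoutFraction = holdoutFraction, sourceType = sourceType,
                 targetType = targetType, seed = seed)
  ws <- seq_len(nSource)^(-exponent)
  wt <- seq_len(nTarget)^(-exponent)
  prob <- outer(ws, wt)
  prob <- pmin(prob * meanEdgeProb / mean(prob), 0.95)
  out <- .finishBipartiteKG(spec, prob, seed)
  out$blocks <- NULL
  out
}
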