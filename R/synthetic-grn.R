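#' Specification for a synthetic linear-Gaussian gene network
#'
#' Parameters of the ground-truth generator used to benchmark Markov
#' blanket recovery. Expression is modeled as a linear-Gaussian structural
#' equation model over a random DAG: each gene is a weighted sum of its
#' parents plus Gaussian noise. Absolute edge coefficients are bounded
#' away from zero (>= 0.3) so the generated distributions stay faithful to
#' the DAG in practice and blanket recovery is a fair test.
#'
#' @param nGenes number of genes (> 0).
#' @param nSamples default sample count for [sampleExpression()]; the
#'   real expression inputs the generator emulates carry 3-8 replicate
#'   values per gene, recovery benchmarks use far more.
#' @param maxParents cap on the number of parents per gene
#'   (must be < `nGenes`).
#' @param edgeProb probability in (0,1) that an admissible parent edge is
#'   present.
#' @param coefRange length-2 magnitude interval for edge coefficients;
#'   `min(coefRange) >= 0.3`. Signs are drawn at random.
#' @param noiseSd positive noise standard deviation.
#' @param seed integer seed.
#' @return an object of class `SyntheticGRNSpec` (a validated list).
#' @seealso [generateDAG()], [sampleExpression()], [trueMarkovBlankets()]
#' @export
grnSpec <- function(nGenes, nSamples = 6L, maxParents = 3L, edgeProb = 0.1,
                    coefRange = c(0.3, 1), noiseSd = 1, seed = 1L) {
  stopifnot(nGenes >= 1L, nSamples >= 1L, maxParents >= 1L)
  if (maxParents >= nGenes && nGenes > 1L)
    stop("maxParents must be smaller than nGenes")
  if (edgeProb <= 0 || edgeProb >= 1) stop("edgeProb must lie in (0, 1)")
  stopifnot(length(coefRange) == 2L, all(coefRange > 0),
            coefRange[1L] <= coefRange[2L])
  if (coefRange[1L] < 0.3)
    stop("min |coefficient| must be >= 0.3 (near-zero effects break faithfulness)")
  stopifnot(noiseSd > 0)
  structure(list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
                 maxParents = as.integer(maxParents), edgeProb = edgeProb,
                 coefRange = as.numeric(coefRange), noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticGRNSpec")
}

.geneIds <- function(n) sprintf("g%03d", seq_len(n))

#' Generate a random DAG with capped in-degree
#'
#' Draws a uniformly random topological order; each gene then selects
#' parents among the earlier genes independently with probability
#' `edgeProb`, truncated to at most `maxParents` (a random subset is kept
#' when the draw exceeds the cap). Deterministic for a fixed seed.
#'
#' @param spec a [grnSpec()].
#' @return a `TrueStructure` list with elements `geneIds`, `dag` (2-column
#'   character matrix, parent -> child), `order` (topological order of
#'   gene ids) and `spec`.
#' @export
generateDAG <- function(spec) {
  stopifnot(inherits(spec, "SyntheticGRNSpec"))
  set.seed(spec$seed)
  n <- spec$nGenes
  ids <- .geneIds(n)
  ord <- sample.int(n)
  parents <- vector("list", n)
  if (n > 1L) {
    for (k in 2:n) {
      earlier <- ord[seq_len(k - 1L)]
      sel <- earlier[runif(k - 1L) < spec$edgeProb]
      if (length(sel) > spec$maxParents)
        sel <- sel[sample.int(length(sel), spec$maxParents)]
      parents[[ord[k]]] <- sort(sel)
    }
  }
  dag <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(parents[[i]]) == 0L) return(NULL)
    cbind(parent = ids[parents[[i]]], child = ids[i])
  }))
  if (is.null(dag)) dag <- matrix(character(), ncol = 2L,
                                  dimnames = list(NULL, c("parent", "child")))
  structure(list(geneIds = ids, dag = dag, order = ids[ord], spec = spec),
            class = "TrueStructure")
}

#' Sample expression data from a linear-Gaussian SEM
#'
#' Genes are sampled in topological order: each gene equals the
#' coefficient-weighted sum of its parents plus independent Gaussian noise
#' of standard deviation `noiseSd`. Coefficients are drawn once per edge,
#' uniformly in magnitude over `coefRange` with random sign, from the same
#' seed, so a fixed seed gives a bit-identical matrix.
#'
#' @param structure a `TrueStructure` from [generateDAG()].
#' @param nSamples number of samples (columns); >= 1.
#' @param coefRange,noiseSd,seed override the values stored in the generator spec.
#' @return numeric matrix genes x samples with gene-id rownames and
#'   sample-id colnames; attribute `"coefficients"` carries the edge
#'   weights actually used.
#' @export
sampleExpression <- function(structure, nSamples = NULL, coefRange = NULL,
                             noiseSd = NULL, seed = NULL) {
  stopifnot(inherits(structure, "TrueStructure"))
  spec <- structure$spec
  if (is.null(nSamples)) nSamples <- spec$nSamples
  if (is.null(coefRange)) coefRange <- spec$coefRange
  if (is.null(noiseSd)) noiseSd <- spec$noiseSd
  if (is.null(seed)) seed <- spec$seed
  if (nSamples < 1L) stop("nSamples must be >= 1")
  set.seed(seed)
  ids <- structure$geneIds
  n <- length(ids)
  dag <- structure$dag
  m <- nrow(dag)
  coef <- if (m) runif(m, coefRange[1L], coefRange[2L]) *
    sample(c(-1, 1), m, replace = TRUE) else numeric()
  x <- matrix(0, nrow = n, ncol = nSamples,
              dimnames = list(ids, sprintf("s%03d", seq_len(nSamples))))
  childIdx <- if (m) match(dag[, "child"], ids) else integer()
  parentIdx <- if (m) match(dag[, "parent"], ids) else integer()
  for (g in structure$order) {
    i <- match(g, ids)
    e <- which(childIdx == i)
    x[i, ] <- rnorm(nSamples, sd = noiseSd)
    for (k in e) x[i, ] <- x[i, ] + coef[k] * x[parentIdx[k], ]
  }
  attr(x, "coefficients") <- if (m)
    data.frame(parent = dag[, "parent"], child = dag[, "child"], coef = coef)
  else data.frame(parent = character(), child = character(), coef = numeric())
  x
}

#' True Markov blankets of a synthetic DAG
#'
#' The Markov blanket of a gene is the union of its parents, its
#' children, and the other parents of its children (spouses), excluding
#' the gene itself.
#'
#' @param structure a `TrueStructure` from [generateDAG()].
#' @return named list mapping each gene id to a sorted character vector.
#' @export
trueMarkovBlankets <- function(structure) {
  stopifnot(inherits(structure, "TrueStructure"))
  ids <- structure$geneIds
  dag <- structure$dag
  mb <- stats::setNames(vector("list", length(ids)), ids)
  for (g in ids) {
    pa <- dag[dag[, "child"] == g, "parent"]
    ch <- dag[dag[, "parent"] == g, "child"]
    sp <- if (length(ch)) dag[dag[, "child"] %in% ch, "parent"] else character()
    mb[[g]] <- sort(setdiff(unique(c(pa, ch, sp)), g))
  }
  mb
}

#' Write / read an expression matrix as CSV
#'
#' Rows are genes, columns samples; the first column holds the gene id
#' and the header row the sample ids.
#'
#' @param x numeric matrix with gene-id rownames.
#' @param path CSV path.
#' @return `writeExpression` returns `path` invisibly; `readExpression`
#'   the numeric matrix.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression CSV needs a gene column plus samples")
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(df[[1L]])
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(x))) stop("gene ids must be unique")
  x
}
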