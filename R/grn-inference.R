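## Fisher-z partial-correlation machinery shared by ciTest() and iamb().
## `C` is the full gene-gene correlation matrix, `n` the sample count.
.partialCor <- function(C, i, j, K) {
  idx <- c(i, j, K)
  S <- C[idx, idx, drop = FALSE]
  Om <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Om)) Om <- solve(S + diag(1e-8, nrow(S)))
  r <- -Om[1L, 2L] / sqrt(Om[1L, 1L] * Om[2L, 2L])
  max(min(r, 1 - 1e-12), -1 + 1e-12)
}

.fisherZ <- function(r, n, nCond) {
  df <- n - nCond - 3L
  z <- atanh(r) * sqrt(df)
  list(statistic = z, pvalue = 2 * pnorm(-abs(z)))
}

#' Fisher-z conditional-independence test
#'
#' Tests independence of genes `i` and `j` given a conditioning set via
#' the partial correlation `rho`: the statistic
#' `z = atanh(rho) * sqrt(n - |cond| - 3)` is referred to the standard
#' normal (two-sided). Requires `n > |cond| + 3` samples; a constant
#' gene yields `pvalue = 1` with a `constant` flag instead of an error.
#'
#' @param i,j gene ids (distinct).
#' @param cond character vector of conditioning gene ids (may be empty);
#'   must exclude `i` and `j`.
#' @param data numeric matrix genes x samples with gene-id rownames.
#' @return list with `statistic` (z), `pvalue`, `constant` (flag).
#' @examples
#' x <- matrix(rnorm(300), 3, 100, dimnames = list(c("a", "b", "c"), NULL))
#' ciTest("a", "b", character(), x)
#' @export
ciTest <- function(i, j, cond = character(), data) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  cond <- as.character(cond)
  if (i == j) stop("i and j must differ")
  if (i %in% cond || j %in% cond) stop("cond must exclude i and j")
  vars <- c(i, j, cond)
  miss <- setdiff(vars, rownames(data))
  if (length(miss)) stop("unknown gene id(s): ", paste(miss, collapse = ", "))
  n <- ncol(data)
  if (n - length(cond) - 3L < 1L)
    stop(sprintf(
      "insufficient samples: need n > |cond| + 3 (n=%d, |cond|=%d)",
      n, length(cond)))
  sub <- data[vars, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds[1:2] == 0)) {
    warning("constant gene in test; returning p = 1")
    return(list(statistic = 0, pvalue = 1, constant = TRUE))
  }
  keep <- c(TRUE, TRUE, sds[-(1:2)] > 0)
  sub <- sub[keep, , drop = FALSE]
  C <- cor(t(sub))
  r <- .partialCor(C, 1L, 2L, seq_len(nrow(sub))[-(1:2)])
  out <- .fisherZ(r, n, sum(keep) - 2L)
  out$constant <- FALSE
  out
}

## Core IAMB on a precomputed correlation matrix. Returns the blanket for
## gene index `t` as indices into rownames(C).
.iambCore <- function(C, n, t, alpha, kmax, ids) {
  p <- nrow(C)
  pval1 <- function(x, K) .fisherZ(.partialCor(C, t, x, K), n, length(K))$pvalue
  B <- integer()
  ## grow: add the maximally associated candidate while it is dependent
  repeat {
    if (length(B) >= kmax) {
      warning(sprintf(
        "blanket of %s truncated at %d members by sample size", ids[t], kmax))
      break
    }
    cand <- setdiff(seq_len(p), c(t, B))
    if (!length(cand)) break
    pv <- vapply(cand, pval1, numeric(1L), K = B)
    best <- cand[order(pv, ids[cand])][1L]
    if (pv[match(best, cand)] < alpha) B <- c(B, best) else break
  }
  ## shrink: drop members independent of the target given the rest
  finalP <- stats::setNames(numeric(length(B)), ids[B])
  repeat {
    removed <- FALSE
    for (x in B[order(ids[B])]) {
      pv <- pval1(x, setdiff(B, x))
      if (pv >= alpha) {
        B <- setdiff(B, x)
        removed <- TRUE
        break
      }
      finalP[ids[x]] <- pv
    }
    if (!removed) break
  }
  list(members = ids[B[order(ids[B])]],
       pvalues = finalP[ids[B[order(ids[B])]]])
}

.condCap <- function(nSamples, maxCondSize = NULL) {
  kmax <- nSamples - 4L
  if (!is.null(maxCondSize)) kmax <- min(kmax, as.integer(maxCondSize))
  kmax
}

#' Discover a Markov blanket by incremental association (IAMB)
#'
#' Grow phase: repeatedly add the candidate gene with the strongest
#' association with the target conditioned on the current blanket
#' (smallest Fisher-z p-value; ties broken lexicographically by gene id)
#' while that p-value falls below `alpha`. Shrink phase: remove any
#' member that is independent of the target given the remaining blanket.
#' The output is deterministic given the data and `alpha`.
#'
#' With very few samples the conditioning-set size is capped at
#' `n - 4` so the Fisher-z degrees of freedom stay positive; at the
#' extreme (cap 0) the procedure degrades to marginal-correlation
#' screening and a warning is emitted.
#'
#' @param target gene id.
#' @param data numeric matrix genes x samples, gene-id rownames, >= 3
#'   samples, no missing values.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param maxCondSize optional additional cap on the conditioning-set
#'   size.
#' @return list of class `MarkovBlanket` with `target`, `members`
#'   (sorted gene ids) and `pvalues` (final per-member p-values).
#' @export
iamb <- function(target, data, alpha = 0.05, maxCondSize = NULL) {
  stopifnot(is.matrix(data), !is.null(rownames(data)), ncol(data) >= 3L,
            !anyNA(data), alpha > 0, alpha < 1)
  ids <- rownames(data)
  if (anyDuplicated(ids)) stop("gene ids must be unique")
  if (!target %in% ids) stop("unknown target gene: ", target)
  if (nrow(data) == 1L)
    return(structure(list(target = target, members = character(),
                          pvalues = numeric()), class = "MarkovBlanket"))
  C <- cor(t(data))
  C[is.na(C)] <- 0
  diag(C) <- 1
  kmax <- .condCap(ncol(data), maxCondSize)
  if (kmax <= 0L) {
    warning("too few samples for conditional tests; marginal screening only")
    kmax <- 0L
  }
  res <- if (kmax == 0L) {
    pv <- vapply(setdiff(seq_along(ids), match(target, ids)), function(x)
      .fisherZ(.partialCor(C, match(target, ids), x, integer()), ncol(data),
               0L)$pvalue, numeric(1L))
    sel <- setdiff(seq_along(ids), match(target, ids))[pv < alpha]
    list(members = sort(ids[sel]),
         pvalues = stats::setNames(pv[pv < alpha][order(ids[sel])],
                                   sort(ids[sel])))
  } else {
    .iambCore(C, ncol(data), match(target, ids), alpha, kmax, ids)
  }
  structure(list(target = target, members = res$members,
                 pvalues = res$pvalues), class = "MarkovBlanket")
}

#' Infer a gene regulatory network from expression data
#'
#' Runs [iamb()] for every gene and joins blankets into an undirected
#' skeleton: edge (u, v) is created when `v` is in MB(u) *or* `u` is in
#' MB(v) (`rule = "OR"`, the default, maximizing regulator recall) or
#' when both hold (`rule = "AND"`). Regulatory activity of a gene is its
#' degree in the resulting network.
#'
#' @param data numeric matrix genes x samples, gene-id rownames.
#' @param alpha significance level for the CI tests.
#' @param rule symmetry rule, `"OR"` or `"AND"`.
#' @param maxCondSize optional conditioning-set cap (see [iamb()]).
#' @return a [GeneRegulatoryNetwork-class].
#' @export
buildGRN <- function(data, alpha = 0.05, rule = c("OR", "AND"),
                     maxCondSize = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(data), !is.null(rownames(data)), ncol(data) >= 3L,
            !anyNA(data))
  ids <- rownames(data)
  blankets <- lapply(ids, iamb, data = data, alpha = alpha,
                     maxCondSize = maxCondSize)
  names(blankets) <- ids
  inMB <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (g in ids) inMB[g, blankets[[g]]$members] <- TRUE
  adj <- if (rule == "OR") inMB | t(inMB) else inMB & t(inMB)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  methods::new("GeneRegulatoryNetwork", graph = g, blankets = blankets,
               alpha = alpha, rule = rule)
}

#' Rank genes by regulatory activity
#'
#' Sorts genes by GRN degree (descending), breaking ties
#' lexicographically by gene id, and returns the top `topK`.
#'
#' @param grn a [GeneRegulatoryNetwork-class].
#' @param topK number of genes to return; must not exceed the node count.
#' @return character vector of gene ids (empty for an empty GRN).
#' @export
rankRegulators <- function(grn, topK) {
  stopifnot(methods::is(grn, "GeneRegulatoryNetwork"))
  act <- regulatoryActivity(grn)
  if (length(act) == 0L) return(character())
  if (topK > length(act)) stop("topK exceeds the number of genes")
  ord <- order(-act, names(act))
  names(act)[ord][seq_len(topK)]
}

#' Mean F1 of recovered Markov blankets against ground truth
#'
#' Per-gene F1 of the recovered members versus the true blanket (1 when
#' both are empty), averaged over genes. Used to benchmark [buildGRN()]
#' on synthetic linear-Gaussian networks.
#'
#' @param blankets named list of `MarkovBlanket` objects or character
#'   vectors, or a [GeneRegulatoryNetwork-class].
#' @param truth named list of character vectors (see
#'   [trueMarkovBlankets()]).
#' @return mean F1 in \[0, 1\].
#' @export
markovBlanketF1 <- function(blankets, truth) {
  if (methods::is(blankets, "GeneRegulatoryNetwork"))
    blankets <- markovBlankets(blankets)
  f1 <- vapply(names(truth), function(g) {
    pred <- blankets[[g]]
    if (is.list(pred)) pred <- pred$members
    pred <- unique(as.character(pred))
    tr <- truth[[g]]
    if (length(pred) == 0L && length(tr) == 0L) return(1)
    tp <- length(intersect(pred, tr))
    if (tp == 0L) return(0)
    prec <- tp / length(pred)
    rec <- tp / length(tr)
    2 * prec * rec / (prec + rec)
  }, numeric(1L))
  mean(f1)
}
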