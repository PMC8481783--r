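#' Learn node embeddings from a walk corpus
#'
#' Deterministic random-walk feature learning: token co-occurrences
#' within a symmetric window over the walk corpus are converted to a
#' positive pointwise-mutual-information (PPMI) matrix, which is
#' factorized by truncated eigendecomposition; node vectors are the
#' leading eigenvectors scaled by the square root of the eigenvalue
#' magnitudes. This is the classical closed-form counterpart of
#' skip-gram walk embeddings and is bit-reproducible for a fixed corpus.
#' When the co-occurrence rank falls short of `dim` the remaining columns
#' are zero-padded (with a message).
#'
#' Component signs are canonicalized (the largest-magnitude loading of
#' each component is made positive) so embeddings do not depend on node
#' ordering.
#'
#' @param walks list of character vectors (see [generateWalks()]).
#' @param dim embedding dimension (default 100, the number of random-walk
#'   features fed to the classifiers).
#' @param window symmetric co-occurrence window (default 10).
#' @param mode embedding algorithm; `"ppmi"` is the deterministic mode
#'   implemented here and is recorded in the metadata.
#' @return a [NodeEmbeddings-class]; rows are the nodes seen in the
#'   corpus, in lexicographic id order.
#' @export
learnEmbeddings <- function(walks, dim = 100L, window = 10L, mode = "ppmi") {
  stopifnot(length(walks) > 0L, dim >= 1L, window >= 1L)
  mode <- match.arg(mode, "ppmi")
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  n <- length(vocab)
  keys <- vector("list", length(walks))
  for (i in seq_along(walks)) {
    w <- match(walks[[i]], vocab)
    L <- length(w)
    kk <- vector("list", min(window, L - 1L))
    for (off in seq_len(min(window, L - 1L))) {
      a <- w[seq_len(L - off)]
      b <- w[seq.int(off + 1L, L)]
      kk[[off]] <- c((a - 1) * n + b, (b - 1) * n + a)
    }
    keys[[i]] <- unlist(kk, use.names = FALSE)
  }
  C <- matrix(as.numeric(tabulate(unlist(keys, use.names = FALSE),
                                  nbins = n * n)), n, n)
  total <- sum(C)
  rs <- rowSums(C)
  ## log PMI computed additively to stay in double range
  P <- log(C) + log(total) - outer(log(rs), log(rs), `+`)
  P[!is.finite(P)] <- 0
  P[P < 0] <- 0
  es <- eigen(P, symmetric = TRUE)
  ord <- order(-abs(es$values), -es$values)
  k <- min(dim, n)
  keep <- ord[seq_len(k)]
  vec <- es$vectors[, keep, drop = FALSE]
  ## canonical signs: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    piv <- which.max(abs(vec[, j]))
    if (vec[piv, j] < 0) vec[, j] <- -vec[, j]
  }
  emb <- vec %*% diag(sqrt(abs(es$values[keep])), k, k)
  padded <- 0L
  if (k < dim) {
    padded <- dim - k
    message("embedding rank ", k, " below dim ", dim, "; zero-padding ",
            padded, " column(s)")
    emb <- cbind(emb, matrix(0, n, padded))
  }
  rownames(emb) <- vocab
  colnames(emb) <- sprintf("f%03d", seq_len(dim))
  methods::new("NodeEmbeddings", vectors = emb, mode = mode,
               meta = list(window = as.integer(window), dim = as.integer(dim),
                           rank = k, padded = padded))
}

#' Combine node embeddings into edge features
#'
#' Element-wise, pair-symmetric combinations of the two endpoint vectors:
#' `hadamard` (product, the default), `average`, `l1` (absolute
#' difference), `l2` (squared difference).
#'
#' @param emb a [NodeEmbeddings-class].
#' @param pairs two-column character matrix or data.frame; every node
#'   must have an embedding (missing nodes raise an error naming them).
#' @param operator one of `"hadamard"`, `"average"`, `"l1"`, `"l2"`.
#' @return numeric matrix |pairs| x dim.
#' @export
edgeFeatures <- function(emb, pairs,
                         operator = c("hadamard", "average", "l1", "l2")) {
  operator <- match.arg(operator)
  stopifnot(methods::is(emb, "NodeEmbeddings"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  v <- emb@vectors
  miss <- setdiff(unique(c(pairs)), rownames(v))
  if (length(miss))
    stop("no embedding for node(s): ", paste(head(miss, 5L), collapse = ", "))
  u <- v[pairs[, 1L], , drop = FALSE]
  w <- v[pairs[, 2L], , drop = FALSE]
  out <- switch(operator,
                hadamard = u * w,
                average = (u + w) / 2,
                l1 = abs(u - w),
                l2 = (u - w)^2)
  rownames(out) <- NULL
  out
}
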