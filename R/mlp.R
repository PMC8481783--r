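## Fully connected feed-forward binary classifier trained by full-batch
## Adam or L-BFGS on the cross-entropy loss with L2 weight decay.
## Two named presets mirror the two architectures used for the
## knowledge-graph link predictors:
##   "deep"    - 10 hidden layers x 100 units, relu, adam
##   "shallow" - 1 hidden layer x 300 units, tanh, lbfgs

.mlpActivations <- c("relu", "tanh")
.mlpSolvers <- c("adam", "lbfgs")

.actFun <- function(kind) switch(kind,
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2))

.mlpInit <- function(sizes, activation, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fanIn <- sizes[l]
    sc <- if (activation == "relu") sqrt(2 / fanIn) else sqrt(1 / fanIn)
    list(W = matrix(rnorm(fanIn * sizes[l + 1L], sd = sc), fanIn),
         b = rep(0, sizes[l + 1L]))
  })
}

.mlpForward <- function(params, X, act) {
  L <- length(params)
  as <- vector("list", L + 1L)
  zs <- vector("list", L)
  as[[1L]] <- X
  for (l in seq_len(L)) {
    zs[[l]] <- sweep(as[[l]] %*% params[[l]]$W, 2L, params[[l]]$b, `+`)
    as[[l + 1L]] <- if (l < L) act$f(zs[[l]]) else zs[[l]]
  }
  list(as = as, zs = zs, prob = 1 / (1 + exp(-as[[L + 1L]])))
}

.mlpGrad <- function(params, X, y, act, decay) {
  n <- nrow(X)
  fw <- .mlpForward(params, X, act)
  L <- length(params)
  grads <- vector("list", L)
  delta <- (fw$prob - y) / n          # dLoss/dz at the output
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fw$as[[l]], delta) + decay * params[[l]]$W,
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(params[[l]]$W)) * act$df(fw$zs[[l - 1L]],
                                                     fw$as[[l]])
  }
  eps <- 1e-12
  loss <- -mean(y * log(fw$prob + eps) + (1 - y) * log(1 - fw$prob + eps)) +
    decay / 2 * sum(vapply(params, function(p) sum(p$W^2), numeric(1L)))
  list(grads = grads, loss = loss)
}

.flatten <- function(params) unlist(lapply(params, function(p) c(p$W, p$b)))

.unflatten <- function(theta, sizes) {
  params <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nW <- sizes[l] * sizes[l + 1L]
    params[[l]] <- list(W = matrix(theta[pos + seq_len(nW)], sizes[l]),
                        b = theta[pos + nW + seq_len(sizes[l + 1L])])
    pos <- pos + nW + sizes[l + 1L]
  }
  params
}

#' Fit a multilayer perceptron link classifier
#'
#' Feed-forward network on edge-feature vectors with a sigmoid output,
#' trained on the binary cross-entropy loss with L2 weight decay. The
#' default decay (0.1) is deliberately firm: link-label sets are small
#' relative to the feature dimension and an underregularized network
#' memorizes pair identities instead of the block geometry. Training is
#' deterministic given the seed.
#'
#' @param X numeric feature matrix (pairs x dim).
#' @param y 0/1 labels.
#' @param hidden integer vector of hidden-layer sizes, e.g. `rep(100, 10)`
#'   for the deep preset or `300` for the shallow one.
#' @param activation `"relu"` or `"tanh"`.
#' @param solver `"adam"` (full-batch, learning rate `lr`) or `"lbfgs"`
#'   (via [stats::optim]).
#' @param maxIter iteration cap.
#' @param lr Adam learning rate.
#' @param decay L2 penalty.
#' @param tol relative loss-improvement tolerance for early stopping
#'   (adam).
#' @param seed integer seed for the weight initialization.
#' @param standardize center/scale features before training. Defaults to
#'   FALSE: walk-embedding features carry an eigenvalue-proportional
#'   scale that acts as an implicit prior over components, and
#'   re-standardizing inflates the noise dimensions.
#' @return object of class `mlpFit`.
#' @export
fitMLP <- function(X, y, hidden = rep(100L, 10L), activation = "relu",
                   solver = "adam", maxIter = 300L, lr = 2e-3, decay = 0.1,
                   tol = 1e-6, seed = 1L, standardize = FALSE) {
  activation <- match.arg(activation, .mlpActivations)
  solver <- match.arg(solver, .mlpSolvers)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X))
    scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  sizes <- c(ncol(X), as.integer(hidden), 1L)
  act <- .actFun(activation)
  params <- .mlpInit(sizes, activation, seed)
  if (solver == "adam") {
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
    v <- m
    prev <- Inf
    stall <- 0L
    for (it in seq_len(maxIter)) {
      gl <- .mlpGrad(params, Xs, y, act, decay)
      for (l in seq_along(params)) {
        for (s in c("W", "b")) {
          g <- gl$grads[[l]][[s]]
          m[[l]][[s]] <- b1 * m[[l]][[s]] + (1 - b1) * g
          v[[l]][[s]] <- b2 * v[[l]][[s]] + (1 - b2) * g^2
          mh <- m[[l]][[s]] / (1 - b1^it)
          vh <- v[[l]][[s]] / (1 - b2^it)
          params[[l]][[s]] <- params[[l]][[s]] - lr * mh / (sqrt(vh) + epsA)
        }
      }
      if (is.finite(prev) && abs(prev - gl$loss) < tol * max(prev, 1e-12)) {
        stall <- stall + 1L
        if (stall >= 10L) break
      } else stall <- 0L
      prev <- gl$loss
    }
  } else {
    theta0 <- .flatten(params)
    fn <- function(th) .mlpGrad(.unflatten(th, sizes), Xs, y, act, decay)$loss
    gr <- function(th) .flatten(.mlpGrad(.unflatten(th, sizes), Xs, y, act,
                                         decay)$grads)
    opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxIter))
    params <- .unflatten(opt$par, sizes)
  }
  structure(list(params = params, sizes = sizes, activation = activation,
                 solver = solver, center = ctr, scale = scl),
            class = "mlpFit")
}

#' @rdname fitMLP
#' @param object a fitted `mlpFit`.
#' @param newX feature matrix to score.
#' @return `predictMLP` returns probabilities in \[0, 1\].
#' @export
predictMLP <- function(object, newX) {
  stopifnot(inherits(object, "mlpFit"))
  newX <- as.matrix(newX)
  Xs <- sweep(sweep(newX, 2L, object$center), 2L, object$scale, `/`)
  fw <- .mlpForward(object$params, Xs, .actFun(object$activation))
  as.numeric(fw$prob)
}
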