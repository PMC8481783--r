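#' Configuration for biased random walks
#'
#' Second-order (node2vec-style) walks: from the current node `v` reached
#' from `t`, the unnormalized probability of stepping to neighbor `x` is
#' `1/p` if `x == t` (return), `1` if `x` is adjacent to `t`, and `1/q`
#' otherwise (in-out exploration). `p = q = 1` reduces to a first-order
#' uniform walk.
#'
#' @param numWalks walks started per node (default 10).
#' @param walkLength nodes per walk (default 80).
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param window co-occurrence window used downstream (default 10).
#' @param epochs corpus passes for stochastic trainers (kept for
#'   completeness; the deterministic embedding mode uses one pass).
#' @param seed integer seed.
#' @return object of class `WalkConfig`.
#' @export
walkConfig <- function(numWalks = 10L, walkLength = 80L, p = 1, q = 1,
                       window = 10L, epochs = 1L, seed = 1L) {
  stopifnot(numWalks >= 1L, walkLength >= 2L, p > 0, q > 0, window >= 1L,
            epochs >= 1L)
  structure(list(numWalks = as.integer(numWalks),
                 walkLength = as.integer(walkLength), p = p, q = q,
                 window = as.integer(window), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "WalkConfig")
}

#' Generate biased random walks over a graph
#'
#' Starts `numWalks` walks of `walkLength` nodes from every non-isolated
#' node (isolated nodes are skipped with a message). Deterministic for a
#' fixed seed.
#'
#' @param kg a [KnowledgeGraph-class] or igraph.
#' @param cfg a [walkConfig()].
#' @return list of character vectors of node ids.
#' @export
generateWalks <- function(kg, cfg = walkConfig()) {
  g <- if (methods::is(kg, "KnowledgeGraph")) kg@graph else kg
  stopifnot(igraph::is_igraph(g), inherits(cfg, "WalkConfig"))
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  set.seed(cfg$seed)
  nm <- igraph::vertex_attr(g, "name")
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  deg <- lengths(adj)
  starts <- which(deg > 0L)
  if (length(starts) < length(deg))
    message(length(deg) - length(starts), " isolated node(s) skipped as walk starts")
  if (!length(starts)) stop("graph has no edges to walk on")
  firstOrder <- cfg$p == 1 && cfg$q == 1
  walks <- vector("list", length(starts) * cfg$numWalks)
  w <- 0L
  for (rep in seq_len(cfg$numWalks)) {
    for (s in starts) {
      path <- integer(cfg$walkLength)
      path[1L] <- s
      nb <- adj[[s]]
      path[2L] <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
      if (cfg$walkLength > 2L) {
        for (step in 3:cfg$walkLength) {
          cur <- path[step - 1L]
          prev <- path[step - 2L]
          nb <- adj[[cur]]
          if (firstOrder || length(nb) == 1L) {
            path[step] <- if (length(nb) == 1L) nb
            else nb[sample.int(length(nb), 1L)]
          } else {
            wgt <- ifelse(nb == prev, 1 / cfg$p,
                          ifelse(nb %in% adj[[prev]], 1, 1 / cfg$q))
            path[step] <- nb[sample.int(length(nb), 1L, prob = wgt)]
          }
        }
      }
      w <- w + 1L
      walks[[w]] <- nm[path]
    }
  }
  walks
}
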