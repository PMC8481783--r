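.cleanIds <- function(x) trimws(as.character(x))

## Collapse ids that differ only by case to the first-seen spelling.
.canonIds <- function(ids) {
  ids <- .cleanIds(ids)
  first <- ids[!duplicated(tolower(ids))]
  stats::setNames(first, tolower(first))[tolower(ids)]
}

#' Construct a typed knowledge graph
#'
#' Builds a simple undirected [KnowledgeGraph-class] from a node table and
#' an edge table. Ids are whitespace-trimmed and duplicate detection is
#' case-insensitive (the first-seen spelling is kept, so mixed-case drug
#' names collapse to one node). Duplicate edges collapse to a single edge;
#' self-loops are rejected.
#'
#' @param nodes data.frame with columns `id` and `type`
#'   (type in `"gene"`, `"disease"`, `"drug"`).
#' @param edges data.frame with columns `source` and `target` (may have
#'   zero rows).
#' @param layer `"generic"`, `"GDKG"` (gene-disease) or `"DDKG"`
#'   (disease-drug); the bipartite invariant of the non-generic layers is
#'   enforced.
#' @return a [KnowledgeGraph-class].
#' @examples
#' knowledgeGraph(data.frame(id = c("g1", "d1", "d2"),
#'                           type = c("gene", "disease", "disease")),
#'                data.frame(source = "g1", target = c("d1", "d2")),
#'                layer = "GDKG")
#' @export
knowledgeGraph <- function(nodes, edges = NULL,
                           layer = c("generic", "GDKG", "DDKG")) {
  layer <- match.arg(layer)
  stopifnot(is.data.frame(nodes), all(c("id", "type") %in% names(nodes)))
  ids <- .canonIds(nodes$id)
  if (any(ids == "")) stop("node ids must be non-empty")
  keep <- !duplicated(tolower(ids))
  vdf <- data.frame(name = ids[keep], type = .cleanIds(nodes$type)[keep],
                    stringsAsFactors = FALSE)
  if (!all(vdf$type %in% .NODE_TYPES))
    stop("node types must be in {gene, disease, drug}")
  lut <- stats::setNames(vdf$name, tolower(vdf$name))
  if (is.null(edges) || nrow(edges) == 0L) {
    edf <- data.frame(source = character(), target = character())
  } else {
    stopifnot(all(c("source", "target") %in% names(edges)))
    s <- .cleanIds(edges$source); t <- .cleanIds(edges$target)
    if (any(s == "") || any(t == "")) stop("edge endpoints must be non-empty")
    unknown <- unique(c(s[!tolower(s) %in% names(lut)],
                        t[!tolower(t) %in% names(lut)]))
    if (length(unknown))
      stop("edge references unknown node(s): ",
           paste(head(unknown, 5L), collapse = ", "))
    s <- lut[tolower(s)]; t <- lut[tolower(t)]
    if (any(s == t)) stop("self-loops are not allowed")
    key <- ifelse(s < t, paste(s, t, sep = "\r"), paste(t, s, sep = "\r"))
    keepE <- !duplicated(key)
    edf <- data.frame(source = s[keepE], target = t[keepE],
                      stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  methods::new("KnowledgeGraph", graph = g, layer = layer)
}

.kgFromIgraph <- function(g, layer) {
  methods::new("KnowledgeGraph", graph = g, layer = layer)
}

#' Build the gene-disease knowledge graph (GDKG)
#'
#' Restricts a gene-to-disease association table to a set of key genes
#' (the maximally regulated genes selected from the GRNs) and assembles
#' the bipartite GDKG. Key genes with no association remain as isolated
#' gene nodes; association rows naming a gene outside `keyGenes` are
#' dropped with a message reporting the count.
#'
#' @param keyGenes character vector of gene ids.
#' @param assoc data.frame with columns `source` (gene) and `target`
#'   (disease).
#' @return a [KnowledgeGraph-class] with `layer = "GDKG"`.
#' @export
buildGDKG <- function(keyGenes, assoc) {
  keyGenes <- unique(.canonIds(keyGenes))
  stopifnot(length(keyGenes) > 0L)
  assoc <- .checkAssoc(assoc)
  inKey <- tolower(assoc$source) %in% tolower(keyGenes)
  if (any(!inKey))
    message(sum(!inKey), " association row(s) dropped: gene not in keyGenes")
  assoc <- assoc[inKey, , drop = FALSE]
  diseases <- unique(.canonIds(assoc$target))
  diseases <- setdiff(diseases, keyGenes)
  nodes <- data.frame(
    id = c(keyGenes, diseases),
    type = c(rep("gene", length(keyGenes)), rep("disease", length(diseases))))
  knowledgeGraph(nodes, assoc, layer = "GDKG")
}

#' Build the disease-drug knowledge graph (DDKG)
#'
#' For each selected disease at most `maxDrugsPerDisease` drugs are
#' retained in the order they appear in the association table (mirroring
#' the "up to ten drugs per disease" construction). Drugs shared between
#' diseases become a single node with one edge per disease.
#'
#' @param diseases character vector of disease ids.
#' @param assoc data.frame with columns `source` (disease) and `target`
#'   (drug).
#' @param maxDrugsPerDisease per-disease drug cap (default 10; 0 gives an
#'   edgeless graph of disease nodes).
#' @return a [KnowledgeGraph-class] with `layer = "DDKG"`.
#' @export
buildDDKG <- function(diseases, assoc, maxDrugsPerDisease = 10L) {
  diseases <- unique(.canonIds(diseases))
  stopifnot(length(diseases) > 0L, maxDrugsPerDisease >= 0L)
  assoc <- .checkAssoc(assoc)
  inKey <- tolower(assoc$source) %in% tolower(diseases)
  if (any(!inKey))
    message(sum(!inKey), " association row(s) dropped: disease not selected")
  assoc <- assoc[inKey, , drop = FALSE]
  if (nrow(assoc)) {
    assoc$source <- .canonIds(assoc$source)
    assoc$target <- .canonIds(assoc$target)
    dup <- duplicated(paste(tolower(assoc$source), tolower(assoc$target)))
    assoc <- assoc[!dup, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(assoc)), assoc$source),
                          function(i) head(i, maxDrugsPerDisease)),
                   use.names = FALSE)
    assoc <- assoc[sort(keep), , drop = FALSE]
  }
  drugs <- setdiff(unique(assoc$target), diseases)
  nodes <- data.frame(
    id = c(diseases, drugs),
    type = c(rep("disease", length(diseases)), rep("drug", length(drugs))))
  knowledgeGraph(nodes, assoc, layer = "DDKG")
}

.checkAssoc <- function(assoc) {
  stopifnot(is.data.frame(assoc))
  nm <- names(assoc)
  if (!all(c("source", "target") %in% nm)) {
    if (ncol(assoc) >= 2L) {
      assoc <- assoc[, 1:2]
      names(assoc) <- c("source", "target")
    } else stop("association table needs columns source, target")
  }
  assoc$source <- .cleanIds(assoc$source)
  assoc$target <- .cleanIds(assoc$target)
  bad <- which(assoc$source == "" | assoc$target == "")
  if (length(bad))
    stop("empty id in association table at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  assoc
}
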