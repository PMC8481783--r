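#' Pipeline configuration
#'
#' Bundles every knob of the expression -> GRN -> key genes -> GDKG ->
#' link prediction -> top diseases -> DDKG -> ranked drugs workflow.
#' Inputs are either file paths / in-memory tables or, for fully
#' self-contained runs, synthetic generator specs.
#'
#' @param expression list of expression matrices (genes x samples,
#'   gene-id rownames) or CSV paths (see [readExpression()]); ignored
#'   when `synthetic` is given.
#' @param geneDiseaseAssoc data.frame or CSV path with columns
#'   `source` (gene), `target` (disease); ignored when synthetic.
#' @param diseaseDrugAssoc data.frame or CSV path with columns
#'   `source` (disease), `target` (drug); ignored when synthetic.
#' @param synthetic optional list with elements `grn` (a [grnSpec()]),
#'   `nDatasets` (expression replicates generated from it), `gdkg` and
#'   `ddkg` (each a [kgSpec()]); gene/disease id vocabularies are shared
#'   across stages automatically.
#' @param grn list: `alpha`, `rule`, `topK`, `merge`
#'   (`"union"`/`"intersection"` of per-dataset top genes),
#'   `nSamples` (samples drawn per synthetic dataset).
#' @param walks a [walkConfig()].
#' @param dim embedding dimension.
#' @param operator edge-feature operator.
#' @param predictor a [predictorConfig()].
#' @param thresholds list: `gdkg` (reporting threshold for gene-disease
#'   candidates, default 0.9) and `ddkg` (disease-drug, default 0.8).
#' @param testFraction,negativeRatio edge-split parameters.
#' @param nTopDiseases cap on diseases carried into the DDKG stage.
#' @param maxDrugsPerDisease per-disease drug cap of the DDKG.
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir optional output directory; stage CSVs and a JSON
#'   manifest are written there.
#' @return object of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression = NULL, geneDiseaseAssoc = NULL,
                           diseaseDrugAssoc = NULL, synthetic = NULL,
                           grn = list(), walks = walkConfig(), dim = 100L,
                           operator = "hadamard",
                           predictor = predictorConfig(),
                           thresholds = list(), testFraction = 0.1,
                           negativeRatio = 0.84, nTopDiseases = 40L,
                           maxDrugsPerDisease = 10L, seed = 1L,
                           outDir = NULL) {
  grnDefaults <- list(alpha = 0.05, rule = "OR", topK = 20L,
                      merge = "union", nSamples = NULL)
  grn <- utils::modifyList(grnDefaults, grn)
  thrDefaults <- list(gdkg = 0.9, ddkg = 0.8)
  thresholds <- utils::modifyList(thrDefaults, thresholds)
  stopifnot(thresholds$gdkg > 0, thresholds$gdkg < 1,
            thresholds$ddkg > 0, thresholds$ddkg < 1,
            grn$merge %in% c("union", "intersection"))
  if (is.null(synthetic)) {
    if (is.null(expression) || is.null(geneDiseaseAssoc))
      stop("provide expression + geneDiseaseAssoc, or a synthetic spec")
    for (e in expression)
      if (is.character(e) && !file.exists(e)) stop("missing file: ", e)
    for (p in list(geneDiseaseAssoc, diseaseDrugAssoc))
      if (is.character(p) && !file.exists(p)) stop("missing file: ", p)
  } else {
    stopifnot(inherits(synthetic$grn, "SyntheticGRNSpec"),
              inherits(synthetic$gdkg, "SyntheticKGSpec"))
    if (is.null(synthetic$nDatasets)) synthetic$nDatasets <- 3L
  }
  structure(list(expression = expression,
                 geneDiseaseAssoc = geneDiseaseAssoc,
                 diseaseDrugAssoc = diseaseDrugAssoc,
                 synthetic = synthetic, grn = grn, walks = walks,
                 dim = as.integer(dim), operator = operator,
                 predictor = predictor, thresholds = thresholds,
                 testFraction = testFraction, negativeRatio = negativeRatio,
                 nTopDiseases = as.integer(nTopDiseases),
                 maxDrugsPerDisease = as.integer(maxDrugsPerDisease),
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

.stageSeed <- function(config, offset) {
  (as.integer(config$seed) * 131L + as.integer(offset)) %% 2147483591L + 1L
}

.loadExpression <- function(config) {
  if (!is.null(config$synthetic)) {
    sp <- config$synthetic$grn
    nd <- config$synthetic$nDatasets
    lapply(seq_len(nd), function(i) {
      spi <- sp
      spi$seed <- .stageSeed(config, 10L + i)
      st <- generateDAG(spi)
      x <- sampleExpression(st, nSamples = config$grn$nSamples)
      attr(x, "structure") <- st
      x
    })
  } else {
    lapply(config$expression, function(e)
      if (is.character(e)) readExpression(e) else e)
  }
}

.restrictPairs <- function(pairs, kg) {
  if (is.null(pairs)) return(NULL)
  ids <- kgNodes(kg)$id
  keep <- pairs[, 1L] %in% ids & pairs[, 2L] %in% ids
  pairs[keep, , drop = FALSE]
}

.loadAssoc <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
}

#' Run the gene-disease (GDKG) stage of the pipeline
#'
#' Infers a GRN per expression dataset, merges the per-dataset top
#' regulators into the key-gene set, builds the GDKG from the
#' gene-disease associations, learns walk embeddings on the training
#' graph, trains the configured predictor and reports candidate
#' gene-disease links above the GDKG threshold.
#'
#' @param config a [pipelineConfig()].
#' @return list: `grns`, `keyGenes`, `gdkg`, `split`, `embeddings`,
#'   `predictor`, `auroc` (held-out), `candidates`, `scored` (all scored
#'   non-edges, ranked), `heldOut` (synthetic runs only).
#' @export
runGDKGStage <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  exprs <- .loadExpression(config)
  if (!length(exprs)) stop("GDKG stage: no expression input")
  grns <- lapply(exprs, buildGRN, alpha = config$grn$alpha,
                 rule = config$grn$rule)
  topSets <- lapply(grns, function(g)
    rankRegulators(g, min(config$grn$topK, igraph::vcount(g@graph))))
  keyGenes <- if (config$grn$merge == "union") Reduce(union, topSets)
  else Reduce(intersect, topSets)
  if (!length(keyGenes)) stop("GDKG stage: key-gene merge is empty")
  heldOut <- NULL
  if (!is.null(config$synthetic)) {
    gen <- generateBipartiteKG(config$synthetic$gdkg)
    assoc <- kgEdges(gen$kg)
    heldOut <- gen$heldOut
  } else {
    assoc <- .loadAssoc(config$geneDiseaseAssoc)
  }
  gdkg <- buildGDKG(keyGenes, assoc)
  if (numEdges(gdkg) == 0L)
    stop("GDKG stage: association table contains none of the key genes (empty GDKG)")
  split <- splitEdges(gdkg, config$testFraction, config$negativeRatio,
                      seed = .stageSeed(config, 20L),
                      forbidden = .restrictPairs(heldOut, gdkg))
  wcfg <- config$walks
  wcfg$seed <- .stageSeed(config, 21L)
  walks <- generateWalks(split@trainGraph, wcfg)
  emb <- learnEmbeddings(walks, dim = config$dim, window = wcfg$window)
  pcfg <- config$predictor
  pcfg$seed <- .stageSeed(config, 22L)
  pred <- trainPredictor(split, emb, pcfg, operator = config$operator)
  evalPairs <- rbind(split@testPositives, split@negatives)
  evalLab <- c(rep(1L, nrow(split@testPositives)),
               rep(0L, nrow(split@negatives)))
  okEv <- if (pred@method == "pa") rep(TRUE, nrow(evalPairs))
  else evalPairs[, 1L] %in% rownames(emb@vectors) &
    evalPairs[, 2L] %in% rownames(emb@vectors)
  auroc <- rocAuroc(evalLab[okEv],
                    predictProbability(pred, evalPairs[okEv, , drop = FALSE]))$auroc
  scored <- predictNewLinks(pred, gdkg, threshold = 1e-9)
  candidates <- scored[scored$probability >= config$thresholds$gdkg, ,
                       drop = FALSE]
  rownames(candidates) <- NULL
  res <- list(grns = grns, keyGenes = sort(keyGenes), gdkg = gdkg,
              split = split, embeddings = emb, predictor = pred,
              auroc = auroc, candidates = candidates, scored = scored,
              heldOut = heldOut)
  if (!is.null(config$outDir)) .writeStage(res, config, "gdkg")
  res
}

#' Run the disease-drug (DDKG) stage of the pipeline
#'
#' Selects the top diseases (those incident to GDKG candidate links
#' above the reporting threshold, topped up with the highest-degree GDKG
#' diseases up to `nTopDiseases`), builds the DDKG under the per-disease
#' drug cap, reruns the link-prediction stack and summarizes the unique
#' candidate drugs with their best probability (descending).
#'
#' @param config a [pipelineConfig()].
#' @param gdkgResult output of [runGDKGStage()].
#' @return list: `diseases`, `ddkg`, `split`, `embeddings`, `predictor`,
#'   `auroc`, `candidates`, `scored`, `drugTable`, `heldOut`.
#' @export
runDDKGStage <- function(config, gdkgResult) {
  stopifnot(inherits(config, "PipelineConfig"))
  nd <- kgNodes(gdkgResult$gdkg)
  candDis <- unique(c(gdkgResult$candidates$source,
                      gdkgResult$candidates$target))
  candDis <- intersect(candDis, nd$id[nd$type == "disease"])
  deg <- igraph::degree(gdkgResult$gdkg@graph)
  disDeg <- sort(deg[nd$id[nd$type == "disease"]], decreasing = TRUE)
  topUp <- names(disDeg)[seq_len(min(config$nTopDiseases, length(disDeg)))]
  diseases <- union(candDis, topUp)
  diseases <- diseases[seq_len(min(length(diseases),
                                   max(config$nTopDiseases, length(candDis))))]
  if (!length(diseases)) stop("DDKG stage: empty disease selection")
  heldOut <- NULL
  if (!is.null(config$synthetic) && !is.null(config$synthetic$ddkg)) {
    gen <- generateBipartiteKG(config$synthetic$ddkg)
    assoc <- kgEdges(gen$kg)
    heldOut <- gen$heldOut
  } else {
    assoc <- .loadAssoc(config$diseaseDrugAssoc)
    if (is.null(assoc)) stop("DDKG stage: no disease-drug associations")
  }
  ddkg <- buildDDKG(diseases, assoc, config$maxDrugsPerDisease)
  if (numEdges(ddkg) == 0L)
    stop("DDKG stage: no drug associations for the selected diseases")
  split <- splitEdges(ddkg, config$testFraction, config$negativeRatio,
                      seed = .stageSeed(config, 30L),
                      forbidden = .restrictPairs(heldOut, ddkg))
  wcfg <- config$walks
  wcfg$seed <- .stageSeed(config, 31L)
  walks <- generateWalks(split@trainGraph, wcfg)
  emb <- learnEmbeddings(walks, dim = config$dim, window = wcfg$window)
  pcfg <- config$predictor
  pcfg$seed <- .stageSeed(config, 32L)
  pred <- trainPredictor(split, emb, pcfg, operator = config$operator)
  evalPairs <- rbind(split@testPositives, split@negatives)
  evalLab <- c(rep(1L, nrow(split@testPositives)),
               rep(0L, nrow(split@negatives)))
  okEv <- if (pred@method == "pa") rep(TRUE, nrow(evalPairs))
  else evalPairs[, 1L] %in% rownames(emb@vectors) &
    evalPairs[, 2L] %in% rownames(emb@vectors)
  auroc <- rocAuroc(evalLab[okEv],
                    predictProbability(pred, evalPairs[okEv, , drop = FALSE]))$auroc
  scored <- predictNewLinks(pred, ddkg, threshold = 1e-9)
  candidates <- scored[scored$probability >= config$thresholds$ddkg, ,
                       drop = FALSE]
  rownames(candidates) <- NULL
  if (nrow(candidates) == 0L)
    warning("DDKG stage: no candidate above the reporting threshold")
  drugTable <- summarizeDrugs(candidates, ddkg)
  res <- list(diseases = sort(diseases), ddkg = ddkg, split = split,
              embeddings = emb, predictor = pred, auroc = auroc,
              candidates = candidates, scored = scored,
              drugTable = drugTable, heldOut = heldOut)
  if (!is.null(config$outDir)) .writeStage(res, config, "ddkg")
  res
}

#' Summarize candidate links into a unique-drug table
#'
#' Deduplicates the drug column of a candidate table: each drug appears
#' once with its best (maximum) probability, sorted descending (ties by
#' drug id).
#'
#' @param candidates data.frame with `source`, `target`, `probability`
#'   (either column may hold the drug).
#' @param ddkg the [KnowledgeGraph-class] the candidates came from (used
#'   to tell drug ids from disease ids); optional if `candidates$target`
#'   is already the drug.
#' @return data.frame `drug`, `probability`.
#' @export
summarizeDrugs <- function(candidates, ddkg = NULL) {
  if (nrow(candidates) == 0L)
    return(data.frame(drug = character(), probability = numeric()))
  drug <- candidates$target
  if (!is.null(ddkg)) {
    nd <- kgNodes(ddkg)
    drugs <- nd$id[nd$type == "drug"]
    drug <- ifelse(candidates$target %in% drugs, candidates$target,
                   candidates$source)
  }
  best <- tapply(candidates$probability, drug, max)
  out <- data.frame(drug = names(best), probability = as.numeric(best),
                    row.names = NULL)
  out <- out[order(-out$probability, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.writeStage <- function(res, config, stage) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(config$outDir, stage)
  cand <- res$candidates
  write.csv(cand[, c("source", "target", "probability", "is_new_edge")],
            paste0(pre, "_candidates.csv"), row.names = FALSE)
  kg <- if (stage == "gdkg") res$gdkg else res$ddkg
  writeKG(kg, paste0(pre, "_edges.csv"), format = "edgelist")
  write.csv(nodeMeasures(kg), paste0(pre, "_node_measures.csv"),
            row.names = FALSE)
  gm <- graphMeasures(kg)
  write.csv(data.frame(measure = c("density", "average_neighbors",
                                   "spectral_gap", "diameter", "girth"),
                       value = c(gm$density, gm$average_neighbors,
                                 gm$spectral_gap, gm$diameter, gm$girth)),
            paste0(pre, "_graph_measures.csv"), row.names = FALSE)
  if (!is.null(res$drugTable))
    write.csv(res$drugTable, paste0(pre, "_ranked_drugs.csv"),
              row.names = FALSE)
  invisible(NULL)
}

#' Run the full drug-repurposing pipeline
#'
#' [runGDKGStage()] followed by [runDDKGStage()], a rendered text report
#' and a JSON manifest (when `outDir` is set).
#'
#' @param config a [pipelineConfig()].
#' @return list with `gdkg`, `ddkg` (the two stage results), `report`
#'   (character vector) and `manifest`.
#' @export
runPipeline <- function(config) {
  g <- runGDKGStage(config)
  d <- runDDKGStage(config, g)
  rep <- pipelineReport(g, d)
  manifest <- list(
    seed = config$seed,
    thresholds = config$thresholds,
    predictor = config$predictor$method,
    embedding_mode = g$embeddings@mode,
    gdkg = list(nodes = numNodes(g$gdkg), edges = numEdges(g$gdkg),
                candidates = nrow(g$candidates), auroc = g$auroc),
    ddkg = list(nodes = numNodes(d$ddkg), edges = numEdges(d$ddkg),
                candidates = nrow(d$candidates), auroc = d$auroc,
                drugs = nrow(d$drugTable)))
  if (!is.null(config$outDir)) {
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(rep, file.path(config$outDir, "report.txt"))
  }
  list(gdkg = g, ddkg = d, report = rep, manifest = manifest)
}

#' Render a human-readable pipeline report
#'
#' @param gdkgResult,ddkgResult stage outputs.
#' @return character vector of report lines (renders even when the
#'   candidate lists are empty).
#' @export
pipelineReport <- function(gdkgResult, ddkgResult = NULL) {
  fmtTop <- function(df, n = 10L) {
    if (nrow(df) == 0L) return("  (none)")
    head <- utils::head(df, n)
    sprintf("  %s -- %s  (p=%.4f)", head$source, head$target,
            head$probability)
  }
  lines <- c(
    "Drug-repurposing pipeline report",
    "================================",
    sprintf("Key genes: %d", length(gdkgResult$keyGenes)),
    sprintf("GDKG: %d nodes, %d edges | held-out AUROC %.4f",
            numNodes(gdkgResult$gdkg), numEdges(gdkgResult$gdkg),
            gdkgResult$auroc),
    sprintf("GDKG candidate links above threshold: %d",
            nrow(gdkgResult$candidates)),
    fmtTop(gdkgResult$candidates))
  if (!is.null(ddkgResult)) {
    lines <- c(lines,
      sprintf("DDKG: %d nodes, %d edges | held-out AUROC %.4f",
              numNodes(ddkgResult$ddkg), numEdges(ddkgResult$ddkg),
              ddkgResult$auroc),
      sprintf("DDKG candidate links above threshold: %d",
              nrow(ddkgResult$candidates)),
      fmtTop(ddkgResult$candidates),
      sprintf("Unique candidate drugs: %d", nrow(ddkgResult$drugTable)),
      if (nrow(ddkgResult$drugTable))
        sprintf("  %s (best p=%.4f)", ddkgResult$drugTable$drug,
                ddkgResult$drugTable$probability)
      else "  (none)")
  }
  lines
}
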