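#' Thresholded confusion counts
#'
#' Standard confusion-matrix counts of probabilistic predictions against
#' 0/1 labels at a decision threshold (default 0.5).
#'
#' @param labels 0/1 vector.
#' @param probabilities numeric vector of the same length.
#' @param threshold decision threshold; predictions >= threshold count as
#'   positive.
#' @return list of class `ConfusionCounts` with `tp`, `tn`, `fp`, `fn`
#'   (summing to the number of pairs) and `accuracy`.
#' @export
confusionCounts <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  if (length(labels) == 0L) stop("empty input")
  stopifnot(all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1)
  tn <- sum(pred == 0L & labels == 0)
  fp <- sum(pred == 1L & labels == 0)
  fn <- sum(pred == 0L & labels == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(labels)),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d (accuracy %.4f)\n",
              x$tp, x$tn, x$fp, x$fn, x$accuracy))
  invisible(x)
}

#' ROC curve and AUROC
#'
#' AUROC is computed as the Mann-Whitney concordance probability -- the
#' probability that a random positive outscores a random negative, ties
#' counting one half -- via the rank formulation. The curve enumerates
#' every distinct score as a threshold (plus the endpoints).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores (higher = more likely positive).
#' @return list with `curve` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auroc`.
#' @export
rocAuroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / np,
                numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nn,
                numeric(1L))
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auroc = auroc)
}

#' Stratified k-fold cross-validation of a link classifier
#'
#' Labeled pairs are assigned to folds stratified by class (so every fold
#' contains both classes at the overall balance); each fold is held out
#' once while the classifier is refit on the rest. Per-fold held-out
#' accuracy (percent, at the 0.5 decision threshold) and AUROC are both
#' reported, along with their means.
#'
#' @param labels 0/1 vector.
#' @param features numeric feature matrix aligned with `labels`.
#' @param cfg a [predictorConfig()] with a feature-based method
#'   (`"pa"` is graph-based and not eligible).
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return list of class `CVReport`: `method`, `fold_accuracy` (%),
#'   `fold_auroc`, `mean_accuracy`, `mean_auroc`, `k`.
#' @export
kFoldCV <- function(labels, features, cfg = predictorConfig(), k = 10L,
                    seed = 1L) {
  stopifnot(inherits(cfg, "PredictorConfig"), cfg$method != "pa",
            nrow(features) == length(labels), k >= 2L,
            all(labels %in% c(0, 1)))
  if (min(table(labels)) < k)
    stop("a class has fewer members than folds; stratification impossible")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- auc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold == f
    model <- .fitModel(features[!hold, , drop = FALSE], labels[!hold], cfg)
    pr <- .predictModel(model, features[hold, , drop = FALSE], cfg)
    acc[f] <- 100 * confusionCounts(labels[hold], pr)$accuracy
    auc[f] <- rocAuroc(labels[hold], pr)$auroc
  }
  structure(list(method = cfg$method, fold_accuracy = acc, fold_auroc = auc,
                 mean_accuracy = mean(acc), mean_auroc = mean(auc),
                 k = as.integer(k)),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("%d-fold CV [%s]: mean accuracy %.2f%%, mean AUROC %.4f\n",
              x$k, x$method, x$mean_accuracy, x$mean_auroc))
  cat("  folds (%):", paste(sprintf("%.2f", x$fold_accuracy), collapse = " "),
      "\n")
  invisible(x)
}
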