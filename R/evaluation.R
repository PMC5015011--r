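#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Hotspot is the positive class. Se = TP/(TP+FN) x 100, Sp = TN/(TN+FP) x
#' 100, Acc = (TP+TN)/N x 100, and MCC is the Matthews correlation
#' coefficient. If any MCC marginal is zero the coefficient is defined as 0
#' (with a warning), the standard convention for degenerate tables.
#'
#' @param tp,fn,fp,tn nonnegative integer confusion counts; alternatively
#'   \code{tp} may be a named vector/list with elements \code{TP, FN, FP,
#'   TN}.
#' @return named numeric vector \code{(Se, Sp, Acc, MCC)}; Se/Sp/Acc in
#'   percent.
#' @examples
#' classMetrics(374, 116, 69, 522)  # Se 76.33, Sp 88.32, Acc 82.89, MCC 0.654
#' @export
classMetrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.null(fn) && (is.list(tp) || !is.null(names(tp)))) {
    cc <- tp
    tp <- cc[["TP"]]; fn <- cc[["FN"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]
  }
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  if (tp + fn == 0) stop("no true hotspots (TP + FN == 0)")
  if (tn + fp == 0) stop("no true coldspots (TN + FP == 0)")
  se <- tp / (tp + fn) * 100
  sp <- tn / (tn + fp) * 100
  acc <- (tp + tn) / sum(counts) * 100
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    warning("MCC denominator is zero (a predicted class is empty); ",
            "defining MCC = 0")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(denom2)
  }
  c(Se = se, Sp = sp, Acc = acc, MCC = mcc)
}

#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted factors/characters over
#'   \code{hotspot}/\code{coldspot}.
#' @return named integer vector \code{(TP, FN, FP, TN)}.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  predicted <- factor(as.character(predicted), levels = CLASS_LEVELS)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' lengths differ")
  c(TP = sum(truth == "hotspot" & predicted == "hotspot"),
    FN = sum(truth == "hotspot" & predicted == "coldspot"),
    FP = sum(truth == "coldspot" & predicted == "hotspot"),
    TN = sum(truth == "coldspot" & predicted == "coldspot"))
}

#' ROC curve and area under it
#'
#' Sweeps a decision threshold over the distinct score values (ties
#' grouped), yielding one (FPR, TPR) point per threshold plus the anchors
#' (0,0) and (1,1); the area is computed by the trapezoidal rule, which
#' equals the rank-statistic (pairwise concordance, ties counted 1/2)
#' formulation.
#'
#' @param scores numeric scores, larger = more hotspot-like (e.g. the
#'   ensemble mean hotspot probability).
#' @param truth true labels (\code{hotspot}/\code{coldspot} or +1/-1).
#' @return list with \code{roc} (data.frame \code{threshold}, \code{fpr},
#'   \code{tpr}) and \code{auc}.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc  # 1
#' @export
rocAuc <- function(scores, truth) {
  if (is.numeric(truth)) truth <- ifelse(truth > 0, "hotspot", "coldspot")
  truth <- factor(as.character(truth), levels = CLASS_LEVELS)
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(truth == "hotspot")
  nNeg <- sum(truth == "coldspot")
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- truth[ord] == "hotspot"
  grp <- cumsum(!duplicated(s))           # ties grouped
  tpCum <- cumsum(pos)
  fpCum <- cumsum(!pos)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tpCum[last] / nPos, 1)
  fpr <- c(0, fpCum[last] / nNeg, 1)
  thr <- c(Inf, s[last], -Inf)
  keep <- !duplicated(data.frame(fpr, tpr))
  roc <- data.frame(threshold = thr[keep], fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

.newEvaluation <- function(records, predictor) {
  counts <- confusionCounts(records$truth, records$predicted)
  r <- rocAuc(records$score, records$truth)
  new("HotspotEvaluation", counts = counts,
      metrics = classMetrics(counts), roc = r$roc, auc = r$auc,
      records = records, predictor = predictor)
}

# Internal: encode a dataset once per needed encoder; per-sequence features
# do not depend on the rest of the dataset, so they can be cached across
# leave-one-out folds and only the SVMs are refitted.
.encodedMatrices <- function(dataset, predictor, table, normalized, overrides) {
  encs <- if (predictor == "ensemble") c("kmer", "dacc", "psednc")
          else predictor
  out <- lapply(encs, function(enc) {
    ov <- overrides[[enc]] %||% list()
    list(encoder = enc,
         x = encodeFeatures(dataset, method = enc,
                            params = utils::modifyList(
                              .DEFAULT_SVM[[enc]]$params,
                              ov$params %||% list()),
                            table = table, normalized = normalized),
         cost = ov$cost %||% .DEFAULT_SVM[[enc]]$cost,
         gamma = ov$gamma %||% .DEFAULT_SVM[[enc]]$gamma)
  })
  names(out) <- encs
  out
}

#' Jackknife (leave-one-out) evaluation
#'
#' For each sequence, trains the chosen predictor on all other sequences
#' (fixed hyperparameters, fixed seed) and predicts the held-out one;
#' aggregates the N predictions into confusion counts, the four summary
#' metrics, and a ROC curve over the held-out hotspot-probability scores.
#' Feature encodings are computed once and cached across folds (they are
#' per-sequence quantities); only the SVMs are refitted in each fold.
#'
#' @param dataset labeled [HotspotDataset-class] with >= 2 sequences per
#'   class.
#' @param predictor \code{"ensemble"} (default) or a single base encoder.
#' @param overrides per-encoder hyperparameter overrides as in
#'   [trainEnsemble()].
#' @param table,normalized property table options.
#' @param seed seed for the probability calibration in every fold.
#' @return a [HotspotEvaluation-class].
#' @export
jackknifeEvaluate <- function(dataset,
                              predictor = c("ensemble", "kmer", "dacc",
                                            "psednc"),
                              overrides = list(),
                              table = loadPropertyTable(),
                              normalized = TRUE, seed = 1L) {
  predictor <- match.arg(predictor)
  y <- factor(classLabels(dataset), levels = CLASS_LEVELS)
  .checkTrainable(y)
  n <- length(dataset)
  encoded <- .encodedMatrices(dataset, predictor, table, normalized, overrides)
  ids <- names(sequences(dataset)) %||% as.character(seq_len(n))
  score <- numeric(n)
  predicted <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    probs <- lapply(encoded, function(e) {
      set.seed(as.integer(seed))
      fit <- e1071::svm(x = e$x[tr, , drop = FALSE], y = y[tr],
                        kernel = "radial", cost = e$cost, gamma = e$gamma,
                        probability = TRUE, scale = FALSE)
      pred <- predict(fit, e$x[i, , drop = FALSE], probability = TRUE)
      attr(pred, "probabilities")[, CLASS_LEVELS, drop = FALSE]
    })
    if (predictor == "ensemble") {
      fused <- fuseProbabilities(unname(probs))
      score[i] <- fused$R[1L, "hotspot"]
      predicted[i] <- as.character(fused$label[1L])
    } else {
      pr <- probs[[1L]]
      score[i] <- pr[1L, "hotspot"]
      predicted[i] <- if (pr[1L, "hotspot"] >= pr[1L, "coldspot"] - 1e-12)
        "hotspot" else "coldspot"
    }
  }
  records <- data.frame(id = ids, truth = as.character(y), score = score,
                        predicted = predicted, stringsAsFactors = FALSE)
  .newEvaluation(records, predictor)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Same contract as [jackknifeEvaluate()] but with seeded stratified k-fold
#' splits instead of leave-one-out; provided for comparison with protocols
#' that report 5-fold results.
#'
#' @inheritParams jackknifeEvaluate
#' @param folds number of folds (default 5).
#' @return a [HotspotEvaluation-class].
#' @export
kfoldEvaluate <- function(dataset,
                          predictor = c("ensemble", "kmer", "dacc",
                                        "psednc"),
                          folds = 5L, overrides = list(),
                          table = loadPropertyTable(), normalized = TRUE,
                          seed = 1L) {
  predictor <- match.arg(predictor)
  y <- factor(classLabels(dataset), levels = CLASS_LEVELS)
  .checkTrainable(y)
  if (any(table(y) < folds))
    stop("each class needs at least as many examples as folds")
  n <- length(dataset)
  encoded <- .encodedMatrices(dataset, predictor, table, normalized, overrides)
  ids <- names(sequences(dataset)) %||% as.character(seq_len(n))
  fold <- .stratifiedFolds(y, folds, seed)
  score <- numeric(n)
  predicted <- character(n)
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    probs <- lapply(encoded, function(e) {
      set.seed(as.integer(seed))
      fit <- e1071::svm(x = e$x[tr, , drop = FALSE], y = y[tr],
                        kernel = "radial", cost = e$cost, gamma = e$gamma,
                        probability = TRUE, scale = FALSE)
      pred <- predict(fit, e$x[te, , drop = FALSE], probability = TRUE)
      attr(pred, "probabilities")[, CLASS_LEVELS, drop = FALSE]
    })
    if (predictor == "ensemble") {
      fused <- fuseProbabilities(unname(probs))
      score[te] <- fused$R[, "hotspot"]
      predicted[te] <- as.character(fused$label)
    } else {
      pr <- probs[[1L]]
      score[te] <- pr[, "hotspot"]
      predicted[te] <- ifelse(pr[, "hotspot"] >= pr[, "coldspot"] - 1e-12,
                              "hotspot", "coldspot")
    }
  }
  records <- data.frame(id = ids, truth = as.character(y), score = score,
                        predicted = predicted, stringsAsFactors = FALSE)
  .newEvaluation(records, predictor)
}

#' @rdname HotspotEvaluation-class
#' @export
setMethod("evalMetrics", "HotspotEvaluation", function(x) x@metrics)

#' @rdname HotspotEvaluation-class
#' @export
setMethod("rocPoints", "HotspotEvaluation", function(x) x@roc)

#' @rdname HotspotEvaluation-class
#' @export
setMethod("auc", "HotspotEvaluation", function(x) x@auc)

#' @rdname HotspotEvaluation-class
#' @export
setMethod("predictionRecords", "HotspotEvaluation", function(x) x@records)

#' @rdname HotspotEvaluation-class
#' @export
setMethod("show", "HotspotEvaluation", function(object) {
  m <- object@metrics
  cat("HotspotEvaluation (", object@predictor, ", n = ",
      nrow(object@records), ")\n", sep = "")
  cat(sprintf("  Se = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.3f  AUC = %.3f\n",
              m[["Se"]], m[["Sp"]], m[["Acc"]], m[["MCC"]], object@auc))
  cc <- object@counts
  cat(sprintf("  TP = %d  FN = %d  FP = %d  TN = %d\n",
              cc[["TP"]], cc[["FN"]], cc[["FP"]], cc[["TN"]]))
})
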