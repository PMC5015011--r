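# Per-encoder default SVM hyperparameters (RBF kernel): the fixed values
# used for all training and evaluation unless overridden.
.DEFAULT_SVM <- list(
  kmer   = list(cost = 2^7,  gamma = 2,    params = list(k = 6L)),
  dacc   = list(cost = 2^3,  gamma = 2^-3, params = list(lag = 6L)),
  psednc = list(cost = 2^13, gamma = 2^3,  params = list(lambda = 7L, w = 0.3)))

.checkTrainable <- function(labels) {
  if (length(labels) == 0L) stop("dataset is unlabeled; cannot train")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("training requires >= 2 examples of each class (got ",
         tab[["hotspot"]], " hotspot, ", tab[["coldspot"]], " coldspot)")
}

#' Train a single-encoding SVM predictor
#'
#' Encodes the training sequences with the requested encoder and fits an
#' RBF-kernel SVM with Platt-scaled probability output. Features are used as
#' produced by the encoders (no rescaling by default): k-mer and PseDNC
#' components already live in [0, 1] and the covariance features are
#' computed on z-scored properties.
#'
#' Default hyperparameters per encoder: kmer C = 2^7, gamma = 2; dacc
#' C = 2^3, gamma = 2^-3; psednc C = 2^13, gamma = 2^3.
#'
#' @param dataset a labeled [HotspotDataset-class] with at least two
#'   examples of each class.
#' @param encoder \code{"kmer"}, \code{"dacc"} or \code{"psednc"}.
#' @param params encoder parameter overrides (see [encodeFeatures()]).
#' @param cost,gamma SVM hyperparameter overrides; \code{NULL} takes the
#'   per-encoder default.
#' @param table property table used by the dacc/psednc encoders.
#' @param normalized use z-scored property values (default).
#' @param scale rescale features inside the SVM (default \code{FALSE}).
#' @param seed integer seed fixing the probability-calibration fold
#'   assignment, so retraining is bit-reproducible.
#' @return a [SvmHotspotModel-class].
#' @export
trainBaseSvm <- function(dataset, encoder = c("kmer", "dacc", "psednc"),
                         params = list(), cost = NULL, gamma = NULL,
                         table = loadPropertyTable(), normalized = TRUE,
                         scale = FALSE, seed = 1L) {
  encoder <- match.arg(encoder)
  .checkTrainable(classLabels(dataset))
  def <- .DEFAULT_SVM[[encoder]]
  params <- utils::modifyList(def$params, params)
  cost <- cost %||% def$cost
  gamma <- gamma %||% def$gamma
  x <- encodeFeatures(dataset, method = encoder, params = params,
                      table = table, normalized = normalized)
  y <- factor(classLabels(dataset), levels = CLASS_LEVELS)
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = x, y = y, kernel = "radial", cost = cost,
                    gamma = gamma, probability = TRUE, scale = scale)
  new("SvmHotspotModel", encoder = encoder, params = params,
      cost = cost, gamma = gamma, fit = fit, table = table,
      useNormalized = normalized, seed = as.integer(seed))
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "SvmHotspotModel", function(object, newdata) {
  x <- encodeFeatures(newdata, method = object@encoder,
                      params = object@params, table = object@table,
                      normalized = object@useNormalized)
  pred <- predict(object@fit, x, probability = TRUE)
  pr <- attr(pred, "probabilities")[, CLASS_LEVELS, drop = FALSE]
  rownames(pr) <- rownames(x)
  pr
})

#' Average the class probabilities of the three base predictors
#'
#' The fusion rule of the ensemble: for each class the fused score R_j is
#' the arithmetic mean of the three members' probabilities for that class,
#' and the predicted label is the class with the larger mean. An exact tie
#' (|R1 - R2| <= 1e-12) resolves to hotspot.
#'
#' @param probas list of exactly three per-member probability outputs; each
#'   either a length-2 vector \code{(P(hotspot), P(coldspot))} or an n x 2
#'   matrix with columns \code{hotspot}, \code{coldspot}. Each pair must sum
#'   to 1 within 1e-6.
#' @return list with \code{R} (n x 2 matrix of fused probabilities, columns
#'   \code{hotspot}, \code{coldspot}) and \code{label} (factor of predicted
#'   classes).
#' @examples
#' fuseProbabilities(list(c(0.9, 0.1), c(0.6, 0.4), c(0.6, 0.4)))
#' @export
fuseProbabilities <- function(probas) {
  if (!is.list(probas) || length(probas) != 3L)
    stop("expected a list of exactly three member probability outputs")
  mats <- lapply(probas, function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    if (ncol(p) != 2L) stop("each member output must have two columns")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      stop("member probabilities must sum to 1 (within 1e-6)")
    unname(p)
  })
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L) stop("member outputs disagree on the number of sequences")
  R <- (mats[[1L]] + mats[[2L]] + mats[[3L]]) / 3
  colnames(R) <- CLASS_LEVELS
  lab <- ifelse(R[, "hotspot"] >= R[, "coldspot"] - 1e-12,
                "hotspot", "coldspot")
  list(R = R, label = factor(lab, levels = CLASS_LEVELS))
}

#' Train the three-member SVM ensemble
#'
#' Fits the kmer, dacc and psednc base predictors on the same labeled
#' dataset (each with its per-encoder default C and gamma unless
#' overridden) and combines them under the average-probability fusion rule.
#'
#' @inheritParams trainBaseSvm
#' @param overrides optional named list of per-encoder overrides, e.g.
#'   \code{list(kmer = list(cost = 4, params = list(k = 3)))}.
#' @return a [SvmElModel-class].
#' @export
trainEnsemble <- function(dataset, overrides = list(),
                          table = loadPropertyTable(), normalized = TRUE,
                          seed = 1L) {
  .checkTrainable(classLabels(dataset))
  members <- lapply(c("kmer", "dacc", "psednc"), function(enc) {
    ov <- overrides[[enc]] %||% list()
    trainBaseSvm(dataset, encoder = enc,
                 params = ov$params %||% list(),
                 cost = ov$cost, gamma = ov$gamma,
                 table = table, normalized = normalized, seed = seed)
  })
  new("SvmElModel", members = members)
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "SvmElModel", function(object, newdata) {
  probas <- lapply(object@members, predictProba, newdata = newdata)
  fuseProbabilities(probas)$R
})

#' Predict hotspot/coldspot labels
#'
#' @param object a trained [SvmElModel-class] (or [SvmHotspotModel-class]).
#' @param newdata sequences to classify.
#' @param ... unused.
#' @return data.frame with columns \code{id}, \code{R1} (mean hotspot
#'   probability), \code{R2}, \code{label}.
#' @export
setMethod("predict", "SvmElModel", function(object, newdata, ...) {
  probas <- lapply(object@members, predictProba, newdata = newdata)
  fused <- fuseProbabilities(probas)
  data.frame(id = rownames(probas[[1L]]) %||% seq_len(nrow(fused$R)),
             R1 = fused$R[, "hotspot"], R2 = fused$R[, "coldspot"],
             label = fused$label, row.names = NULL)
})

#' @rdname predict-SvmElModel-method
#' @export
setMethod("predict", "SvmHotspotModel", function(object, newdata, ...) {
  pr <- predictProba(object, newdata)
  lab <- ifelse(pr[, "hotspot"] >= pr[, "coldspot"] - 1e-12,
                "hotspot", "coldspot")
  data.frame(id = rownames(pr) %||% seq_len(nrow(pr)),
             R1 = pr[, "hotspot"], R2 = pr[, "coldspot"],
             label = factor(lab, levels = CLASS_LEVELS), row.names = NULL)
})

setMethod("show", "SvmHotspotModel", function(object) {
  cat("SvmHotspotModel (", object@encoder, "): C = ", object@cost,
      ", gamma = ", object@gamma, ", ",
      object@fit$tot.nSV, " support vectors\n", sep = "")
})

setMethod("show", "SvmElModel", function(object) {
  cat("SvmElModel: average-probability fusion of 3 base predictors\n")
  for (m in object@members) show(m)
})

# Internal: stratified fold assignment, reproducible under the given seed.
.stratifiedFolds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  assign <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Grid search over SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair on a stratified cross-validation of the
#' encoded training data and returns the pair with the highest mean
#' accuracy. Ties resolve to the smallest C, then the smallest gamma. The
#' default grids are C in 2^(-5, -3, ..., 15) and gamma in
#' 2^(-15, -13, ..., 3).
#'
#' @inheritParams trainBaseSvm
#' @param costGrid,gammaGrid numeric vectors of candidate values.
#' @param folds number of cross-validation folds (default 5).
#' @return list with \code{cost}, \code{gamma}, \code{accuracy} (the best
#'   mean CV accuracy) and \code{grid} (data.frame of all results).
#' @export
gridSearch <- function(dataset, encoder = c("kmer", "dacc", "psednc"),
                       params = list(),
                       costGrid = 2^seq(-5, 15, by = 2),
                       gammaGrid = 2^seq(-15, 3, by = 2),
                       folds = 5L, table = loadPropertyTable(),
                       normalized = TRUE, seed = 1L) {
  encoder <- match.arg(encoder)
  if (length(costGrid) == 0L || length(gammaGrid) == 0L)
    stop("grids must be nonempty")
  if (folds < 2L) stop("'folds' must be >= 2")
  y <- factor(classLabels(dataset), levels = CLASS_LEVELS)
  .checkTrainable(y)
  if (any(table(y) < folds))
    stop("each class needs at least as many examples as folds")
  params <- utils::modifyList(.DEFAULT_SVM[[encoder]]$params, params)
  x <- encodeFeatures(dataset, method = encoder, params = params,
                      table = table, normalized = normalized)
  fold <- .stratifiedFolds(y, folds, seed)
  grid <- expand.grid(gamma = gammaGrid, cost = costGrid)[, c("cost", "gamma")]
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(r) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      set.seed(as.integer(seed) + f)
      fit <- e1071::svm(x = x[tr, , drop = FALSE], y = y[tr],
                        kernel = "radial", cost = grid$cost[r],
                        gamma = grid$gamma[r], scale = FALSE)
      correct <- correct + sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1L, ]
  list(cost = best$cost, gamma = best$gamma, accuracy = best$accuracy,
       grid = grid)
}

#' Save / load a trained ensemble
#'
#' Serializes the ensemble (the three fitted members with their encoder
#' parameters and property table) together with the package version, as a
#' single file. Loading reproduces \code{predictProba} outputs bitwise.
#'
#' @param model a [SvmElModel-class] or [SvmHotspotModel-class].
#' @param path file path.
#' @return \code{saveModel}: the path, invisibly; \code{loadModel}: the
#'   model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(model = model,
               package = "hotspotEL",
               version = as.character(utils::packageVersion("hotspotEL"))),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !is(obj$model, "SvmElModel") &&
      !is(obj$model, "SvmHotspotModel"))
    stop("'", path, "' does not contain a saved hotspotEL model")
  obj$model
}
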