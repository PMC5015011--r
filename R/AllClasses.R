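#' @import methods
NULL

DINUCLEOTIDES <- c("AA","AC","AG","AT","CA","CC","CG","CT",
                   "GA","GC","GG","GT","TA","TC","TG","TT")

DINUC_CLASSES <- c("AA/TT","AC/GT","AG/CT","AT","CA/TG",
                   "CC/GG","CG","GA/TC","GC","TA")

CLASS_LEVELS <- c("hotspot", "coldspot")

#' Dinucleotide physicochemical property table
#'
#' Holds a set of dinucleotide physicochemical properties (by default the 15
#' structural and thermodynamic properties used throughout the package: the
#' six flexibility parameters F-roll .. F-rise, the six structural parameters
#' Roll .. Rise, and Energy, Enthalpy, Entropy), in raw units and as
#' per-property z-scores across the 16 dinucleotides. The auto-cross
#' covariance and pseudo dinucleotide composition encoders consume the
#' z-scored values by default so that properties on very different native
#' scales contribute comparably.
#'
#' @slot propertyNames ordered character vector of property names.
#' @slot raw numeric matrix, properties x 16 dinucleotides, native units.
#' @slot normalized numeric matrix of the same shape; each row has mean 0 and
#'   population standard deviation 1 across the 16 dinucleotides.
#'
#' @seealso [loadPropertyTable()], [readPropertyTable()]
#' @export
setClass("DinucPropertyTable",
  representation(propertyNames = "character",
                 raw = "matrix",
                 normalized = "matrix"))

setValidity("DinucPropertyTable", function(object) {
  msgs <- character()
  p <- length(object@propertyNames)
  for (nm in c("raw", "normalized")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(p, 16L)))
      msgs <- c(msgs, sprintf("'%s' must be %d x 16", nm, p))
    else if (!identical(colnames(m), DINUCLEOTIDES))
      msgs <- c(msgs, sprintf("'%s' columns must be the 16 dinucleotides in lexicographic order", nm))
  }
  if (length(msgs) == 0L) {
    mu <- rowMeans(object@normalized)
    sd16 <- sqrt(rowMeans(object@normalized^2) - mu^2)
    if (any(abs(mu) > 1e-9) || any(abs(sd16 - 1) > 1e-9))
      msgs <- c(msgs, "normalized rows must have mean 0 and population sd 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Labeled (or unlabeled) set of candidate recombination region sequences
#'
#' Couples a [Biostrings::DNAStringSet] of strict-alphabet (A/C/G/T) DNA
#' sequences with per-sequence class labels, \code{"hotspot"} or
#' \code{"coldspot"}. An empty label vector denotes prediction mode
#' (sequences whose class is to be predicted).
#'
#' @slot sequences a \code{DNAStringSet}; every sequence has length >= 2 and
#'   contains only A/C/G/T.
#' @slot labels factor with levels \code{hotspot}, \code{coldspot}; either
#'   empty or one label per sequence.
#'
#' @seealso [HotspotDataset()], [readFastaDna()]
#' @export
setClass("HotspotDataset",
  representation(sequences = "DNAStringSet", labels = "factor"))

setValidity("HotspotDataset", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (length(object@labels) != 0L && length(object@labels) != n)
    msgs <- c(msgs, "labels must be empty or match the number of sequences")
  if (!identical(levels(object@labels), CLASS_LEVELS))
    msgs <- c(msgs, "label levels must be exactly 'hotspot', 'coldspot'")
  if (length(object@labels) && anyNA(object@labels))
    msgs <- c(msgs, "labels must not contain NA")
  w <- Biostrings::width(object@sequences)
  if (n && any(w < 2L))
    msgs <- c(msgs, "all sequences must have length >= 2")
  if (n) {
    freq <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    if (any(freq[, "other"] > 0L))
      msgs <- c(msgs, "sequences must contain only A/C/G/T")
  }
  if (length(msgs)) msgs else TRUE
})

#' Single-encoding SVM predictor
#'
#' A radial-basis-function SVM with Platt-scaled probability output, trained
#' on one of the three sequence encodings (\code{kmer}, \code{dacc} or
#' \code{psednc}). Created by [trainBaseSvm()].
#'
#' @slot encoder one of \code{"kmer"}, \code{"dacc"}, \code{"psednc"}.
#' @slot params encoder parameter list (\code{k}, or \code{lag}, or
#'   \code{lambda} and \code{w}).
#' @slot cost,gamma SVM regularization parameter C and RBF kernel width.
#' @slot fit fitted \code{e1071::svm} object.
#' @slot table the [DinucPropertyTable-class] used at training time.
#' @slot useNormalized logical; whether z-scored property values were used.
#' @slot seed integer seed that fixed the probability-calibration folds.
#' @export
setClass("SvmHotspotModel",
  representation(encoder = "character", params = "list",
                 cost = "numeric", gamma = "numeric",
                 fit = "ANY", table = "DinucPropertyTable",
                 useNormalized = "logical", seed = "integer"))

#' Ensemble of the three single-encoding SVMs
#'
#' Holds the three base predictors in fixed order (kmer, dacc, psednc). The
#' ensemble class probability for each class is the arithmetic mean of the
#' three members' probabilities; the predicted label is the class with the
#' larger mean probability (ties resolved to hotspot).
#'
#' Created by [trainEnsemble()].
#'
#' @slot members list of three [SvmHotspotModel-class] objects.
#' @export
setClass("SvmElModel", representation(members = "list"))

setValidity("SvmElModel", function(object) {
  if (length(object@members) != 3L)
    return("an ensemble has exactly three members")
  enc <- vapply(object@members, function(m) m@encoder, character(1))
  if (!identical(enc, c("kmer", "dacc", "psednc")))
    return("members must be (kmer, dacc, psednc) in that order")
  TRUE
})

#' Classifier evaluation report
#'
#' Confusion counts (hotspot = positive class), the four summary statistics
#' (sensitivity, specificity, accuracy as percentages; Matthews correlation
#' coefficient), the ROC curve and its area, and per-sequence prediction
#' records.
#'
#' @slot counts named integer vector \code{(TP, FN, FP, TN)}.
#' @slot metrics named numeric vector \code{(Se, Sp, Acc, MCC)}.
#' @slot roc data.frame with columns \code{fpr}, \code{tpr}; starts at
#'   (0,0), ends at (1,1), both coordinates nondecreasing.
#' @slot auc area under the ROC curve (trapezoidal rule).
#' @slot records data.frame with one row per sequence: \code{id},
#'   \code{truth}, \code{score} (ensemble mean hotspot probability, or the
#'   base predictor's hotspot probability), \code{predicted}.
#' @slot predictor which predictor was evaluated.
#' @export
setClass("HotspotEvaluation",
  representation(counts = "integer", metrics = "numeric",
                 roc = "data.frame", auc = "numeric",
                 records = "data.frame", predictor = "character"))
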