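#' @rdname HotspotDataset
#' @param x an object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname HotspotDataset
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname DinucPropertyTable-class
#' @param x an object.
#' @export
setGeneric("propertyNames", function(x) standardGeneric("propertyNames"))

#' @rdname DinucPropertyTable-class
#' @param normalized logical; return z-scored values (default) or raw values.
#' @export
setGeneric("propertyValues",
           function(x, normalized = TRUE) standardGeneric("propertyValues"))

#' Per-class probability predictions
#'
#' For a base predictor, the Platt-scaled SVM probabilities for each class;
#' for the ensemble, the arithmetic mean of the three members' probabilities.
#'
#' @param object a trained [SvmHotspotModel-class] or [SvmElModel-class].
#' @param newdata a \code{DNAStringSet}, character vector of sequences, or
#'   [HotspotDataset-class].
#' @return numeric matrix with one row per sequence and columns
#'   \code{hotspot}, \code{coldspot}; rows sum to 1.
#' @export
setGeneric("predictProba",
           function(object, newdata) standardGeneric("predictProba"))

#' @rdname HotspotEvaluation-class
#' @param x an object.
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))

#' @rdname HotspotEvaluation-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname HotspotEvaluation-class
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname HotspotEvaluation-class
#' @export
setGeneric("predictionRecords",
           function(x) standardGeneric("predictionRecords"))
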