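# Default dinucleotide physicochemical property values, one row per property,
# columns the 10 strand-symmetric dinucleotide classes. Six conformational
# flexibility parameters (F-*), six equilibrium structural parameters, and
# three nearest-neighbour thermodynamic parameters (kcal/mol, kcal/mol,
# cal/(mol K)).
.DEFAULT_PROPERTY_CLASSES <- local({
  vals <- rbind(
    "F-roll"   = c( 0.04,  0.06,  0.04,  0.05,  0.04,  0.04,  0.04,  0.05,  0.05,  0.03),
    "F-tilt"   = c( 0.08,  0.07,  0.06,  0.10,  0.06,  0.06,  0.06,  0.07,  0.07,  0.07),
    "F-twist"  = c( 0.07,  0.06,  0.05,  0.07,  0.05,  0.06,  0.05,  0.06,  0.06,  0.05),
    "F-slide"  = c( 6.69,  6.80,  3.47,  9.61,  2.00,  2.99,  2.71,  4.27,  4.21,  1.85),
    "F-shift"  = c( 6.24,  2.91,  2.80,  4.66,  2.88,  2.67,  3.02,  3.58,  2.66,  4.11),
    "F-rise"   = c(21.34, 21.98, 17.48, 24.79, 14.51, 14.25, 14.66, 18.41, 17.31, 14.24),
    "Roll"     = c( 1.05,  2.01,  3.60,  0.61,  5.60,  4.68,  6.02,  2.44,  1.70,  3.50),
    "Tilt"     = c(-1.26,  0.33, -1.66,  0.00,  0.14, -0.77,  0.00,  1.44,  0.00,  0.00),
    "Twist"    = c(35.02, 31.53, 32.29, 30.72, 35.43, 33.54, 33.67, 35.67, 34.07, 36.94),
    "Slide"    = c(-0.18, -0.59, -0.22, -0.68,  0.48, -0.17,  0.44, -0.05, -0.19,  0.04),
    "Shift"    = c( 0.01, -0.02, -0.02,  0.00,  0.01,  0.03,  0.00, -0.01,  0.00,  0.00),
    "Rise"     = c( 3.25,  3.24,  3.32,  3.21,  3.37,  3.36,  3.29,  3.30,  3.27,  3.39),
    "Energy"   = c(-1.00, -1.44, -1.28, -0.88, -1.45, -1.84, -2.17, -1.30, -2.24, -0.58),
    "Enthalpy" = c(-7.60, -8.40, -7.80, -7.20, -8.50, -8.00,-10.60, -8.20, -9.80, -7.20),
    "Entropy"  = c(-21.30,-22.40,-21.00,-20.40,-22.70,-19.90,-27.20,-22.20,-24.40,-21.30))
  colnames(vals) <- DINUC_CLASSES
  vals
})

#' Expand strand-symmetric dinucleotide classes to all 16 dinucleotides
#'
#' A dinucleotide and its reverse complement describe the same base-pair step
#' read from opposite strands, so physicochemical tables list only 10 values:
#' six two-member classes (e.g. \code{AA/TT}) and four self-complementary
#' dinucleotides (\code{AT}, \code{CG}, \code{GC}, \code{TA}). This expands
#' such a 10-value map to a full 16-dinucleotide vector in lexicographic
#' order, assigning each class value to both members.
#'
#' @param classValues named numeric vector; names must be exactly the 10
#'   class labels \code{"AA/TT", "AC/GT", "AG/CT", "AT", "CA/TG", "CC/GG",
#'   "CG", "GA/TC", "GC", "TA"}.
#' @return named numeric vector of length 16 (names \code{AA..TT},
#'   lexicographic).
#' @examples
#' cls <- setNames(1:10, hotspotEL:::DINUC_CLASSES)
#' expandDinucClasses(cls)[c("CA", "TG")]  # both 5
#' @export
expandDinucClasses <- function(classValues) {
  if (is.null(names(classValues)) ||
      !setequal(names(classValues), DINUC_CLASSES) ||
      length(classValues) != 10L)
    stop("'classValues' must be named with exactly the 10 dinucleotide ",
         "class labels: ", paste(DINUC_CLASSES, collapse = ", "))
  out <- setNames(numeric(16L), DINUCLEOTIDES)
  for (cls in DINUC_CLASSES) {
    members <- strsplit(cls, "/", fixed = TRUE)[[1L]]
    out[members] <- classValues[[cls]]
  }
  out
}

#' Z-score a property across the 16 dinucleotides
#'
#' Centers and scales one property's 16 dinucleotide values to mean 0 and
#' population (divide-by-n, n = 16) standard deviation 1. Standardization
#' puts properties whose native scales differ by orders of magnitude on a
#' common footing before they enter covariance and correlation sums.
#'
#' @param values named numeric vector of length 16 (one value per
#'   dinucleotide).
#' @return the z-scored vector, same names.
#' @export
normalizeProperty <- function(values) {
  if (length(values) != 16L)
    stop("expected 16 dinucleotide values, got ", length(values))
  mu <- mean(values)
  sd16 <- sqrt(mean((values - mu)^2))
  if (sd16 == 0)
    stop("property has zero variance across the 16 dinucleotides; ",
         "cannot standardize")
  (values - mu) / sd16
}

.makePropertyTable <- function(raw) {
  normalized <- t(apply(raw, 1L, normalizeProperty))
  dimnames(normalized) <- dimnames(raw)
  new("DinucPropertyTable", propertyNames = rownames(raw),
      raw = raw, normalized = normalized)
}

#' Load the default 15-property dinucleotide table
#'
#' Returns the built-in table of 15 dinucleotide physicochemical properties
#' (flexibility, structure and thermodynamics), expanded from the 10
#' strand-symmetric classes to all 16 dinucleotides and z-scored per
#' property.
#'
#' @return a [DinucPropertyTable-class].
#' @examples
#' tab <- loadPropertyTable()
#' propertyValues(tab, normalized = FALSE)["Twist", "TA"]  # 36.94 degrees
#' @export
loadPropertyTable <- function() {
  raw <- t(apply(.DEFAULT_PROPERTY_CLASSES, 1L, expandDinucClasses))
  colnames(raw) <- DINUCLEOTIDES
  .makePropertyTable(raw)
}

#' Read a dinucleotide property table from TSV
#'
#' Expects a header line naming either the 16 dinucleotides or the 10
#' strand-symmetric classes, then one row per property: property name
#' followed by the values. 10-column tables are expanded with
#' [expandDinucClasses()].
#'
#' @param path path to a tab-separated property file.
#' @return a [DinucPropertyTable-class].
#' @export
readPropertyTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (identical(colnames(m), DINUCLEOTIDES)) {
    raw <- m
  } else if (setequal(colnames(m), DINUC_CLASSES)) {
    raw <- t(apply(m, 1L, function(r) expandDinucClasses(setNames(r, colnames(m)))))
    colnames(raw) <- DINUCLEOTIDES
  } else {
    stop("property file columns must be the 16 dinucleotides or the 10 ",
         "strand-symmetric classes")
  }
  storage.mode(raw) <- "double"
  .makePropertyTable(raw)
}

#' @rdname DinucPropertyTable-class
#' @export
setMethod("propertyNames", "DinucPropertyTable",
          function(x) x@propertyNames)

#' @rdname DinucPropertyTable-class
#' @export
setMethod("propertyValues", "DinucPropertyTable",
          function(x, normalized = TRUE)
            if (normalized) x@normalized else x@raw)

setMethod("show", "DinucPropertyTable", function(object) {
  cat("DinucPropertyTable with", length(object@propertyNames),
      "properties x 16 dinucleotides\n")
  cat("properties:", paste(object@propertyNames, collapse = ", "), "\n")
})
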