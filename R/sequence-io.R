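#' Validate and normalize raw DNA sequences
#'
#' Uppercases the input and enforces the strict A/C/G/T alphabet. Under the
#' default \code{"reject"} policy any other symbol (including IUPAC
#' ambiguity codes such as N) is an error; under \code{"strip-ambiguous"}
#' such symbols are removed. Either way a sequence must retain at least two
#' residues (one dinucleotide). Stripping changes every downstream feature,
#' so it is opt-in, never silent default behaviour.
#'
#' @param x character vector of raw sequences.
#' @param policy \code{"reject"} (default) or \code{"strip-ambiguous"}.
#' @param ids optional identifiers used in error messages; defaults to the
#'   names of \code{x} or the element index.
#' @return character vector of validated, uppercase sequences (names kept).
#' @examples
#' validateDna("acgt")                               # "ACGT"
#' validateDna("ACNGT", policy = "strip-ambiguous")  # "ACGT"
#' @export
validateDna <- function(x, policy = c("reject", "strip-ambiguous"),
                        ids = NULL) {
  policy <- match.arg(policy)
  if (length(x) == 0L) stop("no sequences supplied")
  if (is.null(ids))
    ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
  out <- toupper(x)
  for (i in seq_along(out)) {
    s <- out[[i]]
    if (!nzchar(s)) stop("sequence '", ids[[i]], "' is empty")
    bad <- gsub("[ACGT]", "", s)
    if (nzchar(bad)) {
      if (policy == "reject")
        stop("sequence '", ids[[i]], "' contains non-A/C/G/T symbol(s): ",
             paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "),
             " (use policy = \"strip-ambiguous\" to drop them)")
      out[[i]] <- gsub("[^ACGT]", "", s)
    }
    if (nchar(out[[i]]) < 2L)
      stop("sequence '", ids[[i]], "' has fewer than 2 A/C/G/T residues",
           if (policy == "strip-ambiguous") " after stripping" else "")
  }
  out
}

#' Read DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a \code{DNAStringSet}, uppercases the residues
#' and validates the alphabet. Record order is preserved and the identifier
#' is the header line up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @inheritParams validateDna
#' @return a \code{DNAStringSet} of validated sequences.
#' @export
readFastaDna <- function(path, policy = c("reject", "strip-ambiguous")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop("malformed FASTA '", path, "': ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  clean <- validateDna(as.character(seqs), policy = policy, ids = ids)
  out <- Biostrings::DNAStringSet(clean)
  names(out) <- ids
  out
}

#' Construct a hotspot/coldspot dataset
#'
#' @param sequences a \code{DNAStringSet} or character vector of A/C/G/T
#'   sequences.
#' @param labels optional class labels: a factor or character vector with
#'   values \code{"hotspot"}/\code{"coldspot"}, or a numeric vector with
#'   \code{+1} = hotspot, \code{-1} = coldspot. \code{NULL} gives an
#'   unlabeled (prediction-mode) dataset.
#' @return a [HotspotDataset-class].
#' @examples
#' d <- HotspotDataset(c(h1 = "ACGTACGT", c1 = "AATTAATT"), c(1, -1))
#' classLabels(d)
#' @export
HotspotDataset <- function(sequences, labels = NULL) {
  if (is.character(sequences)) {
    clean <- validateDna(sequences)
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(clean)
    names(sequences) <- nm
  }
  if (is.null(labels)) {
    labels <- factor(character(), levels = CLASS_LEVELS)
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(1, -1)))
      stop("numeric labels must be +1 (hotspot) or -1 (coldspot)")
    labels <- factor(ifelse(labels > 0, "hotspot", "coldspot"),
                     levels = CLASS_LEVELS)
  } else {
    labels <- factor(as.character(labels), levels = CLASS_LEVELS)
    if (anyNA(labels))
      stop("labels must be 'hotspot' or 'coldspot'")
  }
  new("HotspotDataset", sequences = sequences, labels = labels)
}

#' @rdname HotspotDataset
#' @export
setMethod("sequences", "HotspotDataset", function(x) x@sequences)

#' @rdname HotspotDataset
#' @export
setMethod("classLabels", "HotspotDataset", function(x) x@labels)

setMethod("length", "HotspotDataset", function(x) length(x@sequences))

setMethod("show", "HotspotDataset", function(object) {
  n <- length(object@sequences)
  cat("HotspotDataset with", n, "sequences")
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat(" (", tab[["hotspot"]], " hotspot, ", tab[["coldspot"]],
        " coldspot)", sep = "")
  } else cat(" (unlabeled)")
  cat("\n")
  if (n) cat("widths:", paste(range(Biostrings::width(object@sequences)),
                              collapse = "-"), "nt\n")
})

setMethod("[", "HotspotDataset", function(x, i, j, ..., drop = TRUE) {
  lab <- if (length(x@labels)) x@labels[i] else x@labels
  new("HotspotDataset", sequences = x@sequences[i], labels = lab)
})

#' Write sequences of a dataset to FASTA
#'
#' @param x a [HotspotDataset-class] or \code{DNAStringSet}.
#' @param path output file path.
#' @export
writeFastaDna <- function(x, path) {
  if (is(x, "HotspotDataset")) x <- sequences(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

.labelsToNumeric <- function(labels)
  ifelse(labels == "hotspot", 1L, -1L)

#' Write a feature matrix to disk
#'
#' Two dialects are supported. \code{"sparse-svm"} writes the sparse
#' SVM-light/LIBSVM text format, one line per sequence:
#' \code{label index:value ...} with 1-based feature indices and zero
#' components omitted (label \code{+1} = hotspot, \code{-1} = coldspot, or
#' \code{0} for unlabeled rows). \code{"tsv"} writes a dense tab-separated
#' table with a header. Values are written with full \code{\%.17g} precision
#' so a round-trip read reproduces them exactly.
#'
#' @param x numeric feature matrix, one row per sequence (as returned by the
#'   \code{encode*} functions).
#' @param labels optional labels (factor/character \code{hotspot}/
#'   \code{coldspot} or numeric +1/-1), one per row.
#' @param path output file path.
#' @param dialect \code{"sparse-svm"} (default) or \code{"tsv"}.
#' @return the path, invisibly.
#' @export
writeFeatureFile <- function(x, labels = NULL, path,
                             dialect = c("sparse-svm", "tsv")) {
  dialect <- match.arg(dialect)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("got ", length(labels), " labels for ", nrow(x), " feature rows")
    if (!is.numeric(labels)) labels <- .labelsToNumeric(labels)
  }
  if (dialect == "tsv") {
    df <- as.data.frame(x)
    if (is.null(colnames(x)))
      colnames(df) <- paste0("f", seq_len(ncol(x)))
    if (!is.null(labels)) df <- cbind(label = labels, df)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      v <- x[i, ]
      nz <- which(v != 0)
      lab <- if (is.null(labels)) "0"
             else if (labels[i] > 0) "+1" else "-1"
      if (length(nz) == 0L) return(lab)
      paste(lab, paste0(nz, ":", sprintf("%.17g", v[nz]), collapse = " "))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a sparse SVM-light feature file back into a dense matrix
#'
#' @param path file written by [writeFeatureFile()] with
#'   \code{dialect = "sparse-svm"}.
#' @param dim optional number of feature columns; defaults to the largest
#'   index present.
#' @return list with \code{x} (dense numeric matrix) and \code{labels}
#'   (numeric vector of +1/-1/0).
#' @export
readFeatureFile <- function(path, dim = NULL) {
  lines <- readLines(path)
  parsed <- lapply(lines, function(ln) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    lab <- as.numeric(toks[1L])
    if (length(toks) > 1L) {
      kv <- strsplit(toks[-1L], ":", fixed = TRUE)
      idx <- vapply(kv, function(p) as.integer(p[1L]), integer(1))
      val <- vapply(kv, function(p) as.numeric(p[2L]), numeric(1))
    } else {
      idx <- integer(); val <- numeric()
    }
    list(lab = lab, idx = idx, val = val)
  })
  p <- if (is.null(dim)) max(1L, unlist(lapply(parsed, `[[`, "idx"))) else dim
  x <- matrix(0, nrow = length(parsed), ncol = p)
  for (i in seq_along(parsed)) x[i, parsed[[i]]$idx] <- parsed[[i]]$val
  list(x = x, labels = vapply(parsed, `[[`, numeric(1), "lab"))
}
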