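# Internal: coerce encoder input to a named character vector of validated
# sequences.
.asSequenceChar <- function(seqs) {
  if (is(seqs, "HotspotDataset")) seqs <- sequences(seqs)
  if (is(seqs, "DNAStringSet") || is(seqs, "DNAString"))
    seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("unsupported sequence input")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- if (is.null(names(seqs)))
      paste0("seq", seq_along(seqs)) else
      ifelse(nzchar(names(seqs)), names(seqs), paste0("seq", seq_along(seqs)))
  validateDna(seqs)
}

# Internal: 1-based index of each overlapping dinucleotide along a sequence,
# in lexicographic order AA=1 .. TT=16.
.dinucIndex <- function(seq) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  L <- length(b)
  4L * (b[-L] - 1L) + b[-1L]
}

#' K-mer occurrence frequency encoding
#'
#' Represents each sequence by the occurrence frequencies of its overlapping
#' k-mers: the component for k-mer m is count(m) / (L - k + 1), the number
#' of windows. Components are ordered lexicographically (A < C < G < T), so
#' the vector has 4^k components summing to 1. This encoding carries local
#' composition information only; it is invariant to where along the sequence
#' the k-mers occur.
#'
#' @param seqs sequences: a \code{DNAStringSet}, character vector, or
#'   [HotspotDataset-class].
#' @param k k-mer length (default 6).
#' @return numeric matrix, one row per sequence, \code{4^k} columns named by
#'   k-mer.
#' @examples
#' encodeKmer("ACGT", k = 1)  # 0.25 for each base
#' @export
encodeKmer <- function(seqs, k = 6L) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  ch <- .asSequenceChar(seqs)
  L <- nchar(ch)
  if (any(L < k))
    stop("sequence(s) too short for k = ", k, ": ",
         paste(names(ch)[L < k], collapse = ", "))
  dss <- Biostrings::DNAStringSet(ch)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = k)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  x <- counts / (L - k + 1L)
  rownames(x) <- names(ch)
  attr(x, "encoder") <- "kmer"
  attr(x, "params") <- list(k = k)
  x
}

#' Dinucleotide auto-cross covariance (DACC) encoding
#'
#' For each physicochemical property the sequence is viewed as the series of
#' that property's values along its overlapping dinucleotides. The
#' auto-covariance (DAC) component for property u and distance g is
#' \deqn{DAC(u,g) = \frac{1}{L-g-1} \sum_{i=1}^{L-g-1}
#'   (P_u(i) - \bar P_u)(P_u(i+g) - \bar P_u)}
#' where \eqn{\bar P_u} is the mean of the property over all L-1
#' dinucleotide positions of that sequence. The cross-covariance (DCC)
#' component for an ordered property pair (u1, u2) replaces the second
#' factor's property by u2. The feature vector is the DAC block
#' (property-major, then distance 1..lag) followed by the DCC block (ordered
#' pairs in row-major order over the property grid, diagonal skipped, each
#' pair contributing lag consecutive components), so with p properties the
#' dimension is p*lag + p*(p-1)*lag (1350 for the default 15 properties and
#' lag = 6). These covariances capture global sequence-order information
#' that composition-only encodings discard.
#'
#' @inheritParams encodeKmer
#' @param table a [DinucPropertyTable-class]; default [loadPropertyTable()].
#' @param lag maximum dinucleotide distance (default 6).
#' @param normalized use the z-scored property values (default) rather than
#'   raw units.
#' @return numeric matrix, one row per sequence, \code{p*lag + p*(p-1)*lag}
#'   named columns.
#' @export
encodeDacc <- function(seqs, table = loadPropertyTable(), lag = 6L,
                       normalized = TRUE) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be >= 1")
  ch <- .asSequenceChar(seqs)
  L <- nchar(ch)
  short <- L < lag + 2L
  if (any(short))
    stop("sequence(s) too short for lag = ", lag, " (need length >= ",
         lag + 2L, "): ", paste(names(ch)[short], collapse = ", "))
  P <- propertyValues(table, normalized = normalized)
  props <- propertyNames(table)
  p <- length(props)

  dacNames <- as.vector(t(outer(props, seq_len(lag),
                                function(u, g) paste0("DAC.", u, ".lag", g))))
  ord <- expand.grid(u2 = seq_len(p), u1 = seq_len(p))[, c("u1", "u2")]
  ord <- ord[ord$u1 != ord$u2, , drop = FALSE]  # row-major over grid, no diagonal
  dccNames <- unlist(lapply(seq_len(nrow(ord)), function(r)
    paste0("DCC.", props[ord$u1[r]], ".", props[ord$u2[r]], ".lag",
           seq_len(lag))))

  encodeOne <- function(s) {
    idx <- .dinucIndex(s)
    n <- length(idx)                 # L - 1 dinucleotide positions
    V <- P[, idx, drop = FALSE]      # p x n property series
    Dev <- V - rowMeans(V)
    dac <- matrix(0, nrow = p, ncol = lag)
    cross <- vector("list", lag)
    for (g in seq_len(lag)) {
      A <- Dev[, seq_len(n - g), drop = FALSE]
      B <- Dev[, (g + 1L):n, drop = FALSE]
      M <- (A %*% t(B)) / (n - g)    # n - g == L - g - 1 summands
      dac[, g] <- diag(M)
      cross[[g]] <- M
    }
    dccVals <- unlist(lapply(seq_len(nrow(ord)), function(r)
      vapply(seq_len(lag), function(g)
        cross[[g]][ord$u1[r], ord$u2[r]], numeric(1))))
    c(as.vector(t(dac)), dccVals)
  }
  x <- t(vapply(ch, encodeOne, numeric(p * lag + p * (p - 1L) * lag)))
  colnames(x) <- c(dacNames, dccNames)
  rownames(x) <- names(ch)
  attr(x, "encoder") <- "dacc"
  attr(x, "params") <- list(lag = lag, normalized = normalized)
  x
}

#' Pseudo dinucleotide composition (PseDNC) encoding
#'
#' Augments the 16 normalized dinucleotide frequencies f_k with lambda
#' sequence-order correlation factors. The tier-j factor is
#' \deqn{\theta_j = \frac{1}{L-1-j} \sum_{i=1}^{L-1-j}
#'   \Theta(i, i+j)}
#' where \eqn{\Theta} between two dinucleotide positions is the mean over
#' the properties of the squared difference of their (z-scored) property
#' values. Components are
#' \deqn{d_k = \frac{f_k}{\sum f + w \sum \theta},\quad k \le 16;\qquad
#'       d_{16+j} = \frac{w\,\theta_j}{\sum f + w \sum \theta}}
#' with weight w in [0, 1], so the 16 + lambda components are nonnegative
#' and sum to 1. f_k is the dinucleotide count divided by L - 1, hence
#' \eqn{\sum f = 1}.
#'
#' @inheritParams encodeDacc
#' @param lambda number of correlation tiers (default 7).
#' @param w weight of the correlation tiers relative to composition, in
#'   [0, 1] (default 0.3).
#' @return numeric matrix, one row per sequence, \code{16 + lambda} columns.
#' @export
encodePseDnc <- function(seqs, table = loadPropertyTable(), lambda = 7L,
                         w = 0.3, normalized = TRUE) {
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("'lambda' must be >= 1")
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
    stop("'w' must be a single number in [0, 1]")
  ch <- .asSequenceChar(seqs)
  L <- nchar(ch)
  short <- L < lambda + 2L
  if (any(short))
    stop("sequence(s) too short for lambda = ", lambda,
         " (need length >= ", lambda + 2L, "): ",
         paste(names(ch)[short], collapse = ", "))
  P <- propertyValues(table, normalized = normalized)
  # Theta[a, b]: mean squared property difference between dinucleotides a, b
  Theta <- matrix(0, 16L, 16L, dimnames = list(DINUCLEOTIDES, DINUCLEOTIDES))
  for (a in 1:16) Theta[a, ] <- colMeans((P - P[, a])^2)

  encodeOne <- function(s) {
    idx <- .dinucIndex(s)
    n <- length(idx)
    f <- tabulate(idx, nbins = 16L) / n
    theta <- vapply(seq_len(lambda), function(j)
      mean(Theta[cbind(idx[seq_len(n - j)], idx[(j + 1L):n])]), numeric(1))
    denom <- sum(f) + w * sum(theta)
    c(f / denom, w * theta / denom)
  }
  x <- t(vapply(ch, encodeOne, numeric(16L + lambda)))
  colnames(x) <- c(DINUCLEOTIDES, paste0("theta", seq_len(lambda)))
  rownames(x) <- names(ch)
  attr(x, "encoder") <- "psednc"
  attr(x, "params") <- list(lambda = lambda, w = w, normalized = normalized)
  x
}

#' Encode sequences with a named encoder
#'
#' Dispatcher over the three encoders, used by training, evaluation and the
#' command-line interface.
#'
#' @inheritParams encodeDacc
#' @param method \code{"kmer"}, \code{"dacc"} or \code{"psednc"}.
#' @param params list of encoder parameters (\code{k}; \code{lag};
#'   \code{lambda}, \code{w}); missing entries take the encoder defaults
#'   k = 6, lag = 6, lambda = 7, w = 0.3.
#' @return numeric feature matrix (see the individual encoders).
#' @export
encodeFeatures <- function(seqs, method = c("kmer", "dacc", "psednc"),
                           params = list(), table = loadPropertyTable(),
                           normalized = TRUE) {
  method <- match.arg(method)
  switch(method,
    kmer = encodeKmer(seqs, k = params$k %||% 6L),
    dacc = encodeDacc(seqs, table = table, lag = params$lag %||% 6L,
                      normalized = normalized),
    psednc = encodePseDnc(seqs, table = table,
                          lambda = params$lambda %||% 7L,
                          w = params$w %||% 0.3, normalized = normalized))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
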