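#' Uniform and composition-biased nucleotide transition matrices
#'
#' Helpers for building first-order Markov transition matrices over
#' \code{A, C, G, T}. \code{uniformTransition()} gives the memoryless
#' uniform chain. \code{gcBiasedTransition(pGC)} sends probability
#' \code{pGC} to each of C and G and \code{(1 - 2 pGC) / 2} to each of A
#' and T, from every state, producing a GC-content shift visible to
#' composition-based encodings.
#'
#' @param pGC per-step probability of emitting C (and of emitting G), in
#'   (0, 0.5).
#' @return 4 x 4 row-stochastic matrix with dimnames \code{A,C,G,T}.
#' @export
uniformTransition <- function() {
  m <- matrix(0.25, 4L, 4L, dimnames = list(c("A","C","G","T"),
                                            c("A","C","G","T")))
  m
}

#' @rdname uniformTransition
#' @export
gcBiasedTransition <- function(pGC = 0.3) {
  if (pGC <= 0 || pGC >= 0.5) stop("'pGC' must be in (0, 0.5)")
  pAT <- (1 - 2 * pGC) / 2
  m <- matrix(rep(c(pAT, pGC, pGC, pAT), each = 4L), 4L, 4L,
              dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  m
}

.checkTransition <- function(m, what) {
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop("'", what, "' must be a 4 x 4 matrix")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
    stop("'", what, "' rows must be nonnegative and sum to 1")
}

#' Stationary distribution of a nucleotide Markov chain
#'
#' @param transition 4 x 4 row-stochastic matrix.
#' @return numeric vector of length 4 summing to 1 (order A, C, G, T).
#' @export
stationaryDistribution <- function(transition) {
  .checkTransition(transition, "transition")
  e <- eigen(t(transition))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  setNames(v / sum(v), c("A", "C", "G", "T"))
}

# Internal: sample one sequence from a first-order chain.
.sampleMarkov <- function(len, transition, start) {
  cum <- t(apply(transition, 1L, cumsum))
  u <- stats::runif(len)
  b <- integer(len)
  b[1L] <- findInterval(u[1L], cumsum(start)) + 1L
  for (i in 2L:len)
    b[i] <- findInterval(u[i], cum[b[i - 1L], ]) + 1L
  paste(c("A", "C", "G", "T")[b], collapse = "")
}

#' Generate a labeled synthetic dataset from class-specific Markov chains
#'
#' Draws hotspot-like and coldspot-like sequences from two first-order
#' Markov chains over \code{A, C, G, T}, with lengths uniform over
#' \code{lengthRange}. Identifiers encode class and index
#' (\code{hot_001}, \code{cold_001}, ...). The generator exists so the
#' full encode/train/fuse/evaluate pipeline is testable offline: a
#' first-order chain is the minimal model whose class differences are
#' visible to all three encoders (composition to k-mer frequencies, order
#' correlations to the covariance and pseudo-composition features). It
#' makes no claim about real recombination biology.
#'
#' @param nHot,nCold number of sequences per class.
#' @param lengthRange integer vector \code{c(min, max)} of sequence lengths
#'   (default 200-500 nt).
#' @param hotTransition,coldTransition 4 x 4 row-stochastic transition
#'   matrices (defaults: moderately GC-enriched hot class vs uniform cold
#'   class).
#' @param hotStart,coldStart initial base distributions (default: the
#'   chain's stationary distribution).
#' @param seed integer seed; the dataset is a deterministic function of it
#'   (R's default Mersenne-Twister generator).
#' @return a labeled [HotspotDataset-class] of \code{nHot + nCold}
#'   sequences.
#' @examples
#' d <- simulateDataset(5, 5, seed = 1)
#' table(classLabels(d))
#' @export
simulateDataset <- function(nHot, nCold, lengthRange = c(200L, 500L),
                            hotTransition = gcBiasedTransition(0.3),
                            coldTransition = uniformTransition(),
                            hotStart = NULL, coldStart = NULL, seed = 1L) {
  .checkTransition(hotTransition, "hotTransition")
  .checkTransition(coldTransition, "coldTransition")
  if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L] ||
      lengthRange[1L] < 2L)
    stop("'lengthRange' must be c(min, max) with 2 <= min <= max")
  hotStart <- hotStart %||% stationaryDistribution(hotTransition)
  coldStart <- coldStart %||% stationaryDistribution(coldTransition)
  set.seed(as.integer(seed))
  lens <- sample(lengthRange[1L]:lengthRange[2L], nHot + nCold,
                 replace = TRUE)
  seqs <- character(nHot + nCold)
  for (i in seq_len(nHot))
    seqs[i] <- .sampleMarkov(lens[i], hotTransition, hotStart)
  for (i in seq_len(nCold))
    seqs[nHot + i] <- .sampleMarkov(lens[nHot + i], coldTransition,
                                    coldStart)
  names(seqs) <- c(sprintf("hot_%03d", seq_len(nHot)),
                   sprintf("cold_%03d", seq_len(nCold)))
  HotspotDataset(seqs, rep(c("hotspot", "coldspot"), c(nHot, nCold)))
}

#' Benchmark-sized synthetic dataset
#'
#' A fixed study condition used by the integration tests: 490 hotspot-like
#' and 591 coldspot-like sequences (the class sizes of the yeast
#' recombination benchmark), lengths 200-500 nt, with a moderate GC
#' enrichment in the hot class (per-step C and G probability 0.30 vs the
#' uniform 0.25).
#'
#' @param seed integer seed.
#' @return a labeled [HotspotDataset-class] with 1081 sequences.
#' @export
benchmarkMimic <- function(seed = 1L)
  simulateDataset(490L, 591L, seed = seed)

# Internal: long-range copy chain. Each base beyond the first `dist`
# positions repeats the base `dist` positions upstream with probability
# `q`, and is uniform otherwise. Base marginals stay uniform and any
# window shorter than `dist + 1` is i.i.d. uniform, so the signal is a
# pure order correlation concentrated at that distance.
.sampleCopyChain <- function(len, dist, q = 0.5) {
  b <- sample.int(4L, len, replace = TRUE)
  copy <- stats::runif(len) < q
  for (i in (dist + 1L):len)
    if (copy[i]) b[i] <- b[i - dist]
  paste(c("A", "C", "G", "T")[b], collapse = "")
}

# Internal: plant copies of a motif at random non-overlapping-ish positions.
.plantMotif <- function(seq, motif = "AACGTT", copies = 8L) {
  L <- nchar(seq)
  m <- nchar(motif)
  starts <- sample.int(L - m + 1L, copies, replace = FALSE)
  for (s in starts) substr(seq, s, s + m - 1L) <- motif
  seq
}

#' Complementary-signal synthetic dataset
#'
#' Generates a dataset in which the hotspot class carries three distinct
#' sub-signals, each visible to essentially one encoder, planted in
#' disjoint thirds of the hot sequences; the cold class is uniform i.i.d.
#' The thirds are:
#' \describe{
#'   \item{motif}{copies of the composition-balanced hexamer
#'     \code{AACGTT} planted at random positions: a hexamer-frequency
#'     signal for the k-mer member.}
#'   \item{distance-6 copy}{each base repeats the base 6 positions
#'     upstream with probability 1/2. Any 6-mer window spans distances
#'     at most 5, so hexamer frequencies stay uniform (k-mer blind), but
#'     dinucleotides 5-6 apart are correlated: the covariance member's
#'     top lags see it.}
#'   \item{distance-8 copy}{the same construction at distance 8: beyond
#'     the covariance member's maximum lag (a lag-6 dinucleotide pair
#'     spans 7 bases) yet inside the pseudo-composition member's 7
#'     correlation tiers (the tier-7 dinucleotide pair spans 8 bases).}
#' }
#' Each base predictor therefore misclassifies the hot thirds it cannot
#' see while the fused average recovers them; this is the regime in which
#' average-probability fusion beats every single member.
#'
#' @param nHot,nCold class sizes.
#' @param lengthRange sequence length range (default 200-500 nt).
#' @param seed integer seed.
#' @return a labeled [HotspotDataset-class].
#' @export
complementarySignalDataset <- function(nHot, nCold,
                                       lengthRange = c(200L, 500L),
                                       seed = 1L) {
  set.seed(as.integer(seed))
  lens <- sample(lengthRange[1L]:lengthRange[2L], nHot + nCold,
                 replace = TRUE)
  unif <- uniformTransition()
  kind <- rep_len(1:3, nHot)
  seqs <- character(nHot + nCold)
  for (i in seq_len(nHot)) {
    seqs[i] <- switch(kind[i],
      .plantMotif(.sampleMarkov(lens[i], unif, rep(0.25, 4L))),
      .sampleCopyChain(lens[i], dist = 6L),
      .sampleCopyChain(lens[i], dist = 8L))
  }
  for (i in seq_len(nCold))
    seqs[nHot + i] <- .sampleMarkov(lens[nHot + i], unif, rep(0.25, 4L))
  names(seqs) <- c(sprintf("hot_%03d", seq_len(nHot)),
                   sprintf("cold_%03d", seq_len(nCold)))
  HotspotDataset(seqs, rep(c("hotspot", "coldspot"), c(nHot, nCold)))
}
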