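# Independent brute-force reference implementations of the three encodings,
# written as plain position-by-position loops. These exist solely to check
# the package's vectorized encoders and deliberately share no code with them.

oracleBases <- c("A", "C", "G", "T")

oracleAllKmers <- function(k) {
  if (k == 1L) return(oracleBases)
  shorter <- oracleAllKmers(k - 1L)
  unlist(lapply(shorter, function(p) paste0(p, oracleBases)))
}

oracleKmer <- function(seq, k) {
  L <- nchar(seq)
  kmers <- oracleAllKmers(k)
  counts <- setNames(numeric(length(kmers)), kmers)
  for (i in 1:(L - k + 1)) {
    m <- substr(seq, i, i + k - 1)
    counts[m] <- counts[m] + 1
  }
  counts / (L - k + 1)
}

# property value of the dinucleotide starting at position i
oraclePval <- function(seq, i, pvec) pvec[[substr(seq, i, i + 1)]]

# DAC then DCC blocks; P is a properties x 16 matrix (rows named, columns
# the 16 dinucleotides)
oracleDacc <- function(seq, P, lag) {
  L <- nchar(seq)
  props <- rownames(P)
  np <- length(props)
  pbar <- numeric(np)
  for (u in seq_len(np)) {
    s <- 0
    for (j in 1:(L - 1)) s <- s + oraclePval(seq, j, P[u, ])
    pbar[u] <- s / (L - 1)
  }
  dac <- numeric(0)
  for (u in seq_len(np)) {
    for (g in 1:lag) {
      s <- 0
      for (i in 1:(L - g - 1))
        s <- s + (oraclePval(seq, i, P[u, ]) - pbar[u]) *
                 (oraclePval(seq, i + g, P[u, ]) - pbar[u])
      dac <- c(dac, s / (L - g - 1))
    }
  }
  dcc <- numeric(0)
  for (u1 in seq_len(np)) {
    for (u2 in seq_len(np)) {
      if (u1 == u2) next
      for (g in 1:lag) {
        s <- 0
        for (i in 1:(L - g - 1))
          s <- s + (oraclePval(seq, i, P[u1, ]) - pbar[u1]) *
                   (oraclePval(seq, i + g, P[u2, ]) - pbar[u2])
        dcc <- c(dcc, s / (L - g - 1))
      }
    }
  }
  c(dac, dcc)
}

oraclePseDnc <- function(seq, P, lambda, w) {
  L <- nchar(seq)
  np <- nrow(P)
  dinucs <- oracleAllKmers(2L)
  f <- setNames(numeric(16), dinucs)
  for (i in 1:(L - 1)) {
    d <- substr(seq, i, i + 1)
    f[d] <- f[d] + 1
  }
  f <- f / (L - 1)
  bigTheta <- function(i, j) {
    s <- 0
    for (u in 1:np)
      s <- s + (oraclePval(seq, i, P[u, ]) - oraclePval(seq, j, P[u, ]))^2
    s / np
  }
  theta <- numeric(lambda)
  for (jj in 1:lambda) {
    s <- 0
    for (i in 1:(L - 1 - jj)) s <- s + bigTheta(i, i + jj)
    theta[jj] <- s / (L - 1 - jj)
  }
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# AUC as the pairwise concordance statistic (ties count 1/2)
oracleAucConcordance <- function(scores, truth) {
  pos <- which(truth == "hotspot")
  neg <- which(truth == "coldspot")
  s <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

randomDna <- function(len) paste(sample(oracleBases, len, replace = TRUE),
                                 collapse = "")
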