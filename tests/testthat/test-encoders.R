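test_that("k-mer frequencies match window counting", {
  expect_equal(as.vector(encodeKmer("ACGT", k = 1)), rep(0.25, 4))

  x <- encodeKmer("AAAA", k = 2)
  expect_equal(x[1, "AA"], 1.0, ignore_attr = TRUE)
  expect_equal(sum(x[1, -1]), 0)

  # 7 overlapping windows of ACGTACGT: AC CG GT TA appear 2/2/2/1 times
  x <- encodeKmer("ACGTACGT", k = 2)
  expect_equal(x[1, c("AC", "CG", "GT", "TA")],
               c(AC = 2, CG = 2, GT = 2, TA = 1) / 7)
  expect_equal(sum(x), 1)

  expect_error(encodeKmer(c(tiny = "ACG"), k = 6), "tiny")
})

test_that("single-property covariance matches a hand-set term-by-term case", {
  # one synthetic property, raw values: p(AC)=1 p(CG)=2 p(GT)=3 p(TA)=4
  raw <- matrix(0, 1, 16, dimnames = list("p", hotspotEL:::DINUCLEOTIDES))
  raw[1, c("AC", "CG", "GT", "TA")] <- 1:4
  tab <- hotspotEL:::.makePropertyTable(raw)

  seq <- "ACGTAC"   # dinucleotides: AC CG GT TA AC -> p = 1 2 3 4 1
  p <- c(1, 2, 3, 4, 1)
  pbar <- mean(p)
  expected <- sum((p[1:4] - pbar) * (p[2:5] - pbar)) / 4
  got <- encodeDacc(seq, table = tab, lag = 1, normalized = FALSE)
  expect_equal(as.vector(got), expected)  # single property: DAC only
  expect_equal(as.vector(got),
               oracleDacc(seq, propertyValues(tab, FALSE), lag = 1))
})

test_that("encoders equal brute-force references on random sequences", {
  tab <- loadPropertyTable()
  P <- propertyValues(tab)
  set.seed(401)
  for (rep in 1:10) {
    s <- randomDna(sample(30:100, 1))
    expect_equal(as.vector(encodeKmer(s, k = 3)), unname(oracleKmer(s, 3)),
                 tolerance = 1e-10)
    expect_equal(as.vector(encodeDacc(s, tab, lag = 3)),
                 oracleDacc(s, P, lag = 3), tolerance = 1e-10)
    expect_equal(as.vector(encodePseDnc(s, tab, lambda = 4, w = 0.3)),
                 unname(oraclePseDnc(s, P, lambda = 4, w = 0.3)),
                 tolerance = 1e-10)
  }
})

test_that("pseudo-composition reduces to normalized dinucleotide frequencies at w = 0", {
  set.seed(5)
  s <- randomDna(80)
  x <- encodePseDnc(s, lambda = 7, w = 0)
  expect_equal(sum(x[1, 17:23]), 0)
  f <- as.vector(encodeKmer(s, k = 2))   # counts / (L-1), same denominator
  expect_equal(as.vector(x[1, 1:16]), f / sum(f))
  expect_error(encodePseDnc(s, w = 1.5), "'w'")
  expect_error(encodePseDnc(c(short = "ACGTACGT"), lambda = 7), "short")
})

test_that("probability-like vectors sum to one and dimensions follow the contracts", {
  set.seed(6)
  seqs <- vapply(1:5, function(i) randomDna(120), character(1))
  expect_equal(unname(rowSums(encodeKmer(seqs, k = 6))), rep(1, 5),
               tolerance = 1e-9)
  ps <- encodePseDnc(seqs, lambda = 7, w = 0.3)
  expect_equal(unname(rowSums(ps)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(ps >= 0))
  expect_identical(ncol(encodeKmer(seqs[1], k = 6)), 4096L)
  expect_identical(ncol(encodeDacc(seqs[1], lag = 6)), 1350L)
  expect_identical(ncol(ps), 23L)
})

test_that("covariance features vanish on homopolymers", {
  homo <- paste(rep("A", 40), collapse = "")
  expect_equal(max(abs(encodeDacc(homo, lag = 6))), 0)
})

test_that("order-sensitive encodings change under shuffling; k-mer marginals do not", {
  set.seed(77)
  s <- randomDna(100)
  base1 <- encodeKmer(s, k = 1)
  dacc <- encodeDacc(s, lag = 6)
  ps <- encodePseDnc(s, lambda = 7, w = 0.3)
  for (i in 1:20) {
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(as.vector(encodeKmer(sh, k = 1)), as.vector(base1))
    expect_gt(max(abs(encodeDacc(sh, lag = 6) - dacc)), 0)
    expect_gt(max(abs(encodePseDnc(sh, lambda = 7, w = 0.3)[, 17:23] -
                        ps[, 17:23])), 0)
  }
})

test_that("encoding is deterministic: identical input, bitwise-identical vector", {
  s <- c(x = "ACGTACGTACGTACGTACGT")
  expect_identical(encodeKmer(s, 4), encodeKmer(s, 4))
  expect_identical(encodeDacc(s, lag = 5), encodeDacc(s, lag = 5))
  expect_identical(encodePseDnc(s, lambda = 6, w = 0.3),
                   encodePseDnc(s, lambda = 6, w = 0.3))
})
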