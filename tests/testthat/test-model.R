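test_that("a base SVM separates constructed GC-biased data and is seed-reproducible", {
  d <- separableDataset(10)
  m <- trainBaseSvm(d, encoder = "kmer", params = list(k = 2), seed = 3)
  pred <- predict(m, d)
  expect_identical(as.character(pred$label), as.character(classLabels(d)))

  held <- separableDataset(5, seed = 202)
  p1 <- predictProba(m, held)
  m2 <- trainBaseSvm(d, encoder = "kmer", params = list(k = 2), seed = 3)
  expect_identical(p1, predictProba(m2, held))
  # training examples get confident correct probabilities
  pr <- predictProba(m, d)
  expect_true(all(pr[classLabels(d) == "hotspot", "hotspot"] > 0.5))
  expect_true(all(pr[classLabels(d) == "coldspot", "coldspot"] > 0.5))
})

test_that("probability outputs are proper two-class distributions", {
  d <- separableDataset(6)
  for (enc in c("kmer", "dacc", "psednc")) {
    m <- trainBaseSvm(d, encoder = enc, seed = 1)
    pr <- predictProba(m, d)
    expect_equal(unname(rowSums(pr)), rep(1, length(d)), tolerance = 1e-9)
    expect_true(all(pr >= 0 & pr <= 1))
  }
  expect_error(trainBaseSvm(d[classLabels(d) == "hotspot"], "kmer"),
               ">= 2 examples")
  m <- trainBaseSvm(d, encoder = "dacc", seed = 1)
  expect_error(predictProba(m, c(tiny = "ACGT")), "lag")
})

test_that("average-probability fusion follows the documented rule", {
  f <- fuseProbabilities(list(c(0.9, 0.1), c(0.6, 0.4), c(0.6, 0.4)))
  expect_equal(unname(f$R), matrix(c(0.7, 0.3), 1))
  expect_identical(as.character(f$label), "hotspot")

  f <- fuseProbabilities(list(c(0.2, 0.8), c(0.3, 0.7), c(0.1, 0.9)))
  expect_equal(unname(f$R), matrix(c(0.2, 0.8), 1))
  expect_identical(as.character(f$label), "coldspot")

  # exact tie resolves to hotspot
  f <- fuseProbabilities(list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
  expect_identical(as.character(f$label), "hotspot")

  expect_error(fuseProbabilities(list(c(1, 0), c(1, 0))), "three")
  expect_error(fuseProbabilities(list(c(0.9, 0.3), c(0.5, 0.5), c(0.5, 0.5))),
               "sum to 1")
})

test_that("fusion conserves probability and is symmetric in member order", {
  set.seed(9)
  for (i in 1:20) {
    ps <- lapply(1:3, function(j) { p <- runif(1); c(p, 1 - p) })
    f1 <- fuseProbabilities(ps)
    expect_equal(sum(f1$R), 1, tolerance = 1e-9)
    f2 <- fuseProbabilities(ps[c(3, 1, 2)])
    expect_equal(f1$R, f2$R)
  }
})

test_that("the ensemble trains three members and agrees with unanimous members", {
  d <- separableDataset(8)
  ens <- trainEnsemble(d, seed = 2)
  expect_identical(vapply(ens@members, function(m) m@encoder, character(1)),
                   c("kmer", "dacc", "psednc"))
  pred <- predict(ens, d)
  expect_identical(as.character(pred$label), as.character(classLabels(d)))
  expect_equal(pred$R1 + pred$R2, rep(1, length(d)), tolerance = 1e-9)
  # mean of the members' probabilities, by definition of the fusion
  memberMean <- Reduce(`+`, lapply(ens@members, predictProba, newdata = d)) / 3
  expect_equal(unname(predictProba(ens, d)), unname(memberMean))
})

test_that("model persistence round-trips predictions bitwise", {
  d <- separableDataset(6)
  ens <- trainEnsemble(d, seed = 4)
  batch <- separableDataset(4, seed = 303)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(ens, f)
  back <- loadModel(f)
  expect_identical(predictProba(back, batch), predictProba(ens, batch))
})

test_that("grid search maximizes CV accuracy with smallest-C tie-breaking", {
  d <- separableDataset(8)
  one <- gridSearch(d, "kmer", params = list(k = 2), costGrid = 2,
                    gammaGrid = 0.5, folds = 2, seed = 5)
  expect_equal(one$cost, 2)
  expect_equal(one$gamma, 0.5)

  res <- gridSearch(d, "kmer", params = list(k = 2),
                    costGrid = c(1, 8), gammaGrid = c(0.25, 1),
                    folds = 4, seed = 5)
  expect_equal(res$accuracy, 1.0)  # separable data: some point is perfect
  perfect <- res$grid[res$grid$accuracy == res$accuracy, ]
  expect_equal(res$cost, min(perfect$cost))
  expect_equal(res$gamma,
               min(perfect$gamma[perfect$cost == res$cost]))
  expect_error(gridSearch(d, "kmer", costGrid = numeric(), gammaGrid = 1),
               "nonempty")
  expect_error(gridSearch(d, "kmer", folds = 20), "folds")
})
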