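revComp <- function(d) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(d, "")[[1]]), collapse = ""))

test_that("default table holds the published raw property values", {
  tab <- loadPropertyTable()
  raw <- propertyValues(tab, normalized = FALSE)
  expect_identical(dim(raw), c(15L, 16L))
  expect_equal(raw["F-roll", "AA"], 0.04)
  expect_equal(raw["Twist", "TA"], 36.94)
  expect_equal(raw["Entropy", "CG"], -27.20)
  expect_equal(raw["Slide", "CA"], 0.48)
  expect_equal(raw["Slide", "TG"], 0.48)   # class expansion
  expect_equal(raw["F-roll", "TT"], 0.04)
})

test_that("class expansion covers all 16 dinucleotides with strand symmetry", {
  cls <- setNames(as.numeric(1:10),
                  c("AA/TT","AC/GT","AG/CT","AT","CA/TG",
                    "CC/GG","CG","GA/TC","GC","TA"))
  v <- expandDinucClasses(cls)
  expect_setequal(names(v), hotspotEL:::DINUCLEOTIDES)
  expect_length(v, 16L)
  for (d in names(v)) expect_equal(v[[d]], v[[revComp(d)]])
  expect_error(expandDinucClasses(cls[-1]), "class labels")
})

test_that("per-property z-scores have mean 0, population sd 1, and strand symmetry", {
  tab <- loadPropertyTable()
  P <- propertyValues(tab, normalized = TRUE)
  expect_true(all(abs(rowMeans(P)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(P^2) - rowMeans(P)^2) - 1) < 1e-9))
  for (d in colnames(P))
    expect_equal(P[, d], P[, revComp(d)], ignore_attr = TRUE)
})

test_that("normalization matches a direct-summation oracle and is idempotent", {
  tab <- loadPropertyTable()
  raw <- propertyValues(tab, normalized = FALSE)["F-slide", ]
  # spreadsheet-style recomputation: explicit sums over the 16 values
  m <- 0; for (v in raw) m <- m + v; m <- m / 16
  ss <- 0; for (v in raw) ss <- ss + (v - m)^2
  s <- sqrt(ss / 16)
  expect_equal(propertyValues(tab)["F-slide", "AT"], (9.61 - m) / s,
               tolerance = 1e-12)

  z <- normalizeProperty(raw)
  expect_equal(normalizeProperty(z), z, tolerance = 1e-9)
  expect_error(normalizeProperty(setNames(rep(1, 16),
                                          hotspotEL:::DINUCLEOTIDES)),
               "zero variance")
})

test_that("property TSV files round-trip, in 16- and 10-column layouts", {
  tab <- loadPropertyTable()
  raw <- propertyValues(tab, normalized = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cbind(property = rownames(raw), as.data.frame(raw)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(propertyValues(readPropertyTable(f), FALSE), raw,
               tolerance = 1e-12)

  cls <- hotspotEL:::.DEFAULT_PROPERTY_CLASSES
  writeLines(c(paste(c("property", colnames(cls)), collapse = "\t"),
               vapply(rownames(cls), function(r)
                 paste(c(r, cls[r, ]), collapse = "\t"), character(1))), f)
  expect_equal(propertyValues(readPropertyTable(f), FALSE), raw,
               tolerance = 1e-12)
})
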