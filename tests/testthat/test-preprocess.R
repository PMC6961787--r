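test_that("feature tables survive a write/read round trip and reject bad input", {
  v <- matrix(c(1.25, NA, 3e-7, 4123.5, 5, 6), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  m <- OmicsMatrix(v)
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(m, path)
  back <- readFeatureTable(path)
  expect_identical(omicsValues(back), omicsValues(m))
  expect_identical(sum(is.na(omicsValues(back))), 1L)

  empty <- tempfile(); writeLines(character(), empty)
  expect_error(readFeatureTable(empty), "empty")
  dup <- tempfile()
  writeLines(c("feature_id\ts1\ts1", "f1\t1\t2"), dup)
  expect_error(readFeatureTable(dup), "duplicate sample ids")
  bad <- tempfile()
  writeLines(c("feature_id\ts1\ts2", "f1\t1\tx7"), bad)
  expect_error(readFeatureTable(bad), "f1.*s2")
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  two <- OmicsMatrix(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                            dimnames = list(paste0("f", 1:3),
                                            c("a", "b"))))
  out <- omicsValues(quantileNormalize(two))
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  set.seed(42)
  x <- OmicsMatrix(matrix(rexp(300), 50, 6))
  q1 <- quantileNormalize(x)
  v1 <- omicsValues(q1)
  sorted <- apply(v1, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(omicsValues(quantileNormalize(q1)), v1, tolerance = 1e-10)
  # fixed point: columns already sharing a distribution are unchanged
  same <- OmicsMatrix(matrix(c(1, 5, 9, 9, 1, 5), 3, 2))
  expect_equal(omicsValues(quantileNormalize(same)), omicsValues(same))
  withNA <- OmicsMatrix(matrix(c(1, NA, 3, 4), 2, 2))
  expect_error(quantileNormalize(withNA), "complete matrix")
})

test_that("log2 transform applies the offset and guards its contract", {
  m <- OmicsMatrix(matrix(c(7, 0, 1, 3), 2, 2))
  out <- log2Transform(m)
  expect_equal(unname(omicsValues(out)[1, 1]), 3)
  expect_equal(unname(omicsValues(out)[2, 1]), 0)
  expect_identical(scaleTag(out), "log2")
  expect_error(log2Transform(out), "log2")
  expect_error(log2Transform(OmicsMatrix(matrix(-2, 1, 1))), "positive")
})

test_that("probe collapse averages per symbol on the current scale", {
  v <- matrix(c(4, 6, 2, 10, 20, 30,
                8, 10, 4, 12, 22, 32), 6, 2,
              dimnames = list(paste0("p", 1:6), c("s1", "s2")))
  map <- c(p1 = "geneB", p2 = "geneB", p3 = "geneA", p4 = "geneC",
           p5 = "geneC", p6 = "geneC")
  out <- collapseProbes(OmicsMatrix(v, scaleTag = "log2"), map)
  ov <- omicsValues(out)
  expect_identical(rownames(ov), c("geneA", "geneB", "geneC"))
  expect_equal(unname(ov["geneB", ]), c(5, 9))
  expect_equal(unname(ov["geneC", ]), c(20, 22))
  expect_identical(colnames(ov), c("s1", "s2"))
  # unmapped probes are dropped with a message
  expect_message(collapseProbes(OmicsMatrix(v), map[1:4]), "dropped")
  expect_error(collapseProbes(OmicsMatrix(v), c(zz = "g")), "no probe")
})

test_that("low-mean gene filter matches a brute-force sort and breaks ties by id", {
  set.seed(7)
  v <- matrix(rnorm(20 * 6, mean = 8), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  m <- OmicsMatrix(v)
  out <- filterLowMeanGenes(m, 0.10)
  expect_identical(nrow(omicsValues(out)), 18L)
  survivors <- names(sort(rowMeans(v), decreasing = TRUE))[1:18]
  expect_setequal(featureIds(out), survivors)
  # survivors keep their original relative order
  expect_identical(featureIds(out),
                   rownames(v)[rownames(v) %in% survivors])
  expect_identical(omicsValues(filterLowMeanGenes(m, 0)), v)
  # exact tie on the minimum mean: the larger id is dropped first
  tied <- matrix(c(5, 5, 9, 5, 5, 9), 3, 2,
                 dimnames = list(c("aa", "ab", "zz"), c("s1", "s2")))
  kept <- featureIds(filterLowMeanGenes(OmicsMatrix(tied), 1 / 3))
  expect_identical(kept, c("aa", "zz"))
  expect_error(filterLowMeanGenes(m, 1), "fraction")
})

test_that("missingness filter applies a strict 80% rule and is monotone", {
  v <- matrix(1, 3, 16, dimnames = list(c("m1", "m2", "m3"), NULL))
  v[1, 1:13] <- NA                     # 81.25% -> dropped
  v[2, 1:12] <- NA                     # 75%    -> kept
  out <- filterMissingMetabolites(OmicsMatrix(v), 0.80)
  expect_identical(featureIds(out), c("m2", "m3"))
  # exactly 80% missing is retained (strict inequality)
  w <- matrix(1, 1, 10, dimnames = list("m", NULL))
  w[1, 1:8] <- NA
  expect_identical(nrow(omicsValues(
    filterMissingMetabolites(OmicsMatrix(w), 0.80))), 1L)
  # monotone in the threshold
  set.seed(9)
  z <- matrix(rnorm(30 * 10), 30, 10)
  z[runif(300) < 0.5] <- NA
  zm <- OmicsMatrix(z)
  for (th in c(0.3, 0.5, 0.7)) {
    strict <- featureIds(filterMissingMetabolites(zm, th))
    loose <- featureIds(filterMissingMetabolites(zm, th + 0.2))
    expect_true(all(strict %in% loose))
  }
  # complete matrix passes through untouched
  full <- OmicsMatrix(matrix(1:12, 3, 4))
  expect_identical(omicsValues(filterMissingMetabolites(full)),
                   omicsValues(full))
})

test_that("PCA centers features, orders components and reconstructs the data", {
  # rank-1 data: a single direction carries all variance
  s <- seq(-3, 3, length.out = 8)
  v <- outer(c(1, 2, -1, 0.5), s)
  rownames(v) <- paste0("f", 1:4); colnames(v) <- paste0("s", 1:8)
  pc <- pcaScores(OmicsMatrix(v), nComponents = 2)
  expect_equal(pc$explainedVariance[1], 1, tolerance = 1e-12)

  set.seed(3)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  full <- pcaScores(OmicsMatrix(x), nComponents = 7)
  expect_true(all(diff(full$explainedVariance) <= 1e-12))
  expect_lte(sum(full$explainedVariance), 1 + 1e-12)
  # reconstruction: scores %*% t(loadings) gives the centered data
  centered <- t(scale(t(x), center = TRUE, scale = FALSE))
  rec <- t(full$scores %*% t(full$loadings))
  expect_equal(rec, centered, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(full$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  # sample reordering leaves scores invariant up to the same reordering
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  shuffled <- pcaScores(OmicsMatrix(x[, perm]), nComponents = 3)
  orig <- pcaScores(OmicsMatrix(x), nComponents = 3)
  expect_equal(shuffled$scores[colnames(x), ], orig$scores,
               tolerance = 1e-8)
  expect_error(pcaScores(OmicsMatrix(x), 9), "nComponents")
  # missing cells are mean-imputed for the decomposition only
  xm <- x; xm[2, 5] <- NA
  expect_silent(pcaScores(OmicsMatrix(xm), 2))
})
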