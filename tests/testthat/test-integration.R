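test_that("a noiseless additive pair is flagged as a degenerate perfect fit", {
  g <- c(1, 2, 3, 4, 5, 1.5, 2.5, 3.5, 4.5, 5.5)
  p <- rep(0:1, each = 5)
  m <- 1 + 2 * g + 3 * p                    # no interaction, no noise
  fit <- fitPairInteractionModel(g, m, p)
  expect_identical(fit@flag, "zero_residual_variance")
  expect_equal(fit@beta4, 0, tolerance = 1e-10)
  expect_equal(fit@tBeta4, 0)
  expect_true(is.na(fit@pInteraction))
  expect_equal(fit@beta1, 1, tolerance = 1e-10)
  expect_equal(fit@beta2, 2, tolerance = 1e-10)
  expect_equal(fit@beta3, 3, tolerance = 1e-10)
})

test_that("an opposite-slope pair recovers beta4 as the slope difference", {
  set.seed(31)
  p <- rep(0:1, each = 8)
  g <- rnorm(16, mean = 8)
  m <- ifelse(p == 0, g, -g) + rnorm(16, 0, 0.05)
  fit <- fitPairInteractionModel(g, m, p)
  expect_identical(fit@flag, "ok")
  expect_equal(fit@beta4, -2, tolerance = 0.05)
  expect_lt(fit@pInteraction, 1e-6)
  expect_equal(fit@beta4, oracleSlopeDiff(g, m, p), tolerance = 1e-12)
})

test_that("fitted coefficients match the normal-equations oracle on seeded fixtures", {
  for (seed in 1:10) {
    fx <- makePairFixture(seed, missing = if (seed %% 2) 2L else 0L)
    fit <- fitPairInteractionModel(fx$g, fx$m, fx$p)
    o <- oracleNormalEquations(fx$g, fx$m, fx$p)
    expect_equal(c(fit@beta1, fit@beta2, fit@beta3, fit@beta4), o$beta,
                 tolerance = 1e-10)
    expect_equal(fit@seBeta4, o$se4, tolerance = 1e-10)
    expect_equal(fit@pInteraction, o$p4, tolerance = 1e-10)
    expect_identical(fit@residualDf, fit@nUsed - 4L)
  }
})

test_that("degenerate designs and small samples are flagged, not fitted", {
  p <- rep(0:1, each = 8)
  gConst <- c(rep(3, 8), rnorm(8))
  expect_identical(fitPairInteractionModel(gConst, rnorm(16), p)@flag,
                   "rank_deficient")
  m <- rnorm(16); m[1:4] <- NA               # group 1 drops to 4 samples
  fit <- fitPairInteractionModel(rnorm(16), m, p)
  expect_identical(fit@flag, "insufficient_samples")
  expect_true(is.na(fit@pInteraction))
})

test_that("group correlations follow the closed rank form on the n = 8 grid", {
  # identity permutation
  expect_equal(groupCorrelation(1:8, (1:8) * 2 + 3), 1.0)
  # Sum d^2 = 8: 1 - 48/504
  expect_equal(round(groupCorrelation(1:8, c(3, 2, 1, 4, 5, 6, 7, 8)), 3),
               0.905)
  # Sum d^2 = 164: 1 - 984/504, the magnitude of a printed correlation
  mPerm <- c(7, 8, 6, 5, 4, 3, 1, 2)
  expect_identical(sum((mPerm - 1:8)^2), 164)
  expect_equal(round(groupCorrelation(1:8, mPerm), 3), -0.952)
  # the rank method ignores monotone distortion; linear does not
  g <- c(1.2, 5.3, 2.2, 8.8, 4.1, 6.6, 7.9, 3.3)
  expect_equal(groupCorrelation(g, exp(g), method = "rank"), 1.0)
  expect_lt(groupCorrelation(g, exp(g), method = "linear"), 1.0)
  expect_true(is.na(groupCorrelation(1:8, rep(2, 8))))
  expect_error(groupCorrelation(1:2, 1:2), "3 complete")
})

test_that("differential correlation is the signed group-2 minus group-1 difference", {
  expect_equal(diffCorrelation(0.905, -0.857), -1.762)
  expect_equal(diffCorrelation(0.762, -0.952), -1.714)
  expect_equal(diffCorrelation(0.4, 0.4), 0)
  expect_true(is.na(diffCorrelation(NA, 0.5)))
  expect_true(is.na(diffCorrelation(0.5, NA)))
})

test_that("the screen agrees pairwise with the single-pair fit and correlations", {
  d <- generatePairedDataset(synthConfig(nGenes = 12, nMetabolites = 8,
                                         nDeGenes = 4,
                                         nInteractingPairs = 3,
                                         missingRate = 0.15, seed = 17))
  tbl <- screenAllPairs(d$expression, d$metabolites, d$design)
  expect_identical(nrow(tbl), 12L * 8L)
  p <- as.numeric(groupLabels(d$design)) - 1
  ve <- omicsValues(d$expression); vm <- omicsValues(d$metabolites)
  idx <- c(1, 8, 20, 41, 67, 96)
  for (i in idx) {
    row <- tbl[i, ]
    g <- ve[row$gene_id, ]; m <- vm[row$metabolite_id, ]
    fit <- fitPairInteractionModel(g, m, p)
    expect_identical(row$flag, fit@flag)
    if (fit@flag == "ok") {
      expect_equal(row$beta4, fit@beta4, tolerance = 1e-10)
      expect_equal(row$p_interaction, fit@pInteraction,
                   tolerance = 1e-10)
      expect_equal(row$se_beta4, fit@seBeta4, tolerance = 1e-10)
      # beta4 identity: joint fit equals the per-group slope difference
      expect_equal(row$beta4, oracleSlopeDiff(g, m, p),
                   tolerance = 1e-10)
    }
    if (row$flag != "insufficient_samples") {
      keep <- !is.na(m)
      r1 <- groupCorrelation(g[p == 0 & keep], m[p == 0 & keep])
      r2 <- groupCorrelation(g[p == 1 & keep], m[p == 1 & keep])
      expect_equal(row$r_group1, r1, tolerance = 1e-12)
      expect_equal(row$r_group2, r2, tolerance = 1e-12)
      expect_equal(row$diff_corr, diffCorrelation(r1, r2),
                   tolerance = 1e-12)
    }
  }
  # output order: decreasing |diff_corr|, NA-flagged rows last
  dc <- abs(tbl$diff_corr)
  expect_true(all(diff(dc[!is.na(dc)]) <= 1e-12))
})

test_that("screen output is invariant to input row and column order", {
  d <- generatePairedDataset(synthConfig(nGenes = 10, nMetabolites = 6,
                                         nDeGenes = 0,
                                         nInteractingPairs = 2,
                                         missingRate = 0.1, seed = 23))
  tbl <- screenAllPairs(d$expression, d$metabolites, d$design)
  ve <- omicsValues(d$expression); vm <- omicsValues(d$metabolites)
  set.seed(1)
  e2 <- OmicsMatrix(ve[sample(nrow(ve)), sample(ncol(ve))],
                    scaleTag = "log2")
  m2 <- OmicsMatrix(vm[sample(nrow(vm)), ])
  tbl2 <- screenAllPairs(e2, m2, d$design)
  expect_equal(tbl, tbl2, tolerance = 1e-12)
})

test_that("vacuous thresholds select every non-degenerate pair and selection is monotone", {
  d <- generatePairedDataset(synthConfig(nGenes = 8, nMetabolites = 6,
                                         nDeGenes = 0,
                                         nInteractingPairs = 2,
                                         missingRate = 0.1, seed = 29))
  vac <- screenAllPairs(d$expression, d$metabolites, d$design,
                        corrThreshold = 0, pThreshold = 1)
  expect_identical(vac$selected, vac$flag == "ok" &
                     !is.na(vac$diff_corr) & abs(vac$diff_corr) > 0)
  # monotonicity: loosening either threshold never drops a selection
  base <- selectAssociations(vac, 1.0, 0.001)
  looseP <- selectAssociations(vac, 1.0, 0.01)
  looseC <- selectAssociations(vac, 0.5, 0.001)
  expect_true(all(!base$selected | looseP$selected))
  expect_true(all(!base$selected | looseC$selected))
})

test_that("assays are aligned by pairing key, with sorted alignment only on request", {
  set.seed(41)
  p <- rep(0:1, each = 5)
  g <- rnorm(10); m <- ifelse(p == 0, g, -g) + rnorm(10, 0, 0.1)
  expr <- OmicsMatrix(matrix(g, 1, 10,
                             dimnames = list("gene1", paste0("E", 1:10))),
                      scaleTag = "log2")
  met <- OmicsMatrix(matrix(m, 1, 10,
                            dimnames = list("met1", paste0("M", 1:10))))
  design <- SampleDesign(
    c(paste0("E", 1:10), paste0("M", 1:10)),
    factor(rep(c("group1", "group2", "group1", "group2"), c(5, 5, 5, 5)),
           levels = c("group1", "group2")),
    pairingId = c(paste0("P", 1:10), paste0("P", 1:10)))
  tbl <- screenAllPairs(expr, met, design)
  expect_identical(tbl$flag, "ok")
  expect_equal(tbl$beta4, -2, tolerance = 0.2)

  # without a shared pairing key the screen refuses to guess
  designNoKey <- SampleDesign(
    c(paste0("E", 1:10), paste0("M", 1:10)),
    factor(rep(c("group1", "group2", "group1", "group2"), c(5, 5, 5, 5)),
           levels = c("group1", "group2")))
  expect_error(screenAllPairs(expr, met, designNoKey), "pairing")
  expect_warning(
    tbl2 <- screenAllPairs(expr, met, designNoKey,
                           allowSortedAlignment = TRUE),
    "sorted")
  expect_equal(tbl2$beta4, tbl$beta4, tolerance = 1e-12)
})

test_that("the P-value histogram covers [0,1] and counts every finite P", {
  d <- generatePairedDataset(synthConfig(nGenes = 10, nMetabolites = 10,
                                         nDeGenes = 0,
                                         nInteractingPairs = 0,
                                         missingRate = 0, seed = 37))
  tbl <- screenAllPairs(d$expression, d$metabolites, d$design)
  h <- pairPValueHistogram(tbl)
  expect_identical(nrow(h), 20L)
  expect_equal(h$bin_high - h$bin_low, rep(0.05, 20))
  expect_identical(sum(h$count), sum(!is.na(tbl$p_interaction)))
  expect_error(pairPValueHistogram(tbl, binWidth = 0.07), "binWidth")
})
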