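grid <- seq(850, 1200, by = 1)

test_that("pcaScreen flags a constructed far-off sample and nothing else", {
  # 10 samples on a perfect 1-D line in spectral space + one far outlier
  set.seed(21)
  direction <- runif(351)
  scores1d <- seq(-1, 1, length.out = 10)
  X <- outer(scores1d, direction)
  X <- rbind(X, 8 * direction)      # far beyond the in-line spread
  s <- SpectrumSet(X, grid, sampleIds = c(paste0("s", 1:10), "far"))
  expect_warning(res <- pcaScreen(s, nComponents = 1, alpha = 0.05),
                 "far")
  expect_identical(res$sampleId[res$outlier], "far")

  ev <- attr(res, "explainedVariance")
  expect_lte(sum(ev), 1 + 1e-12)
  expect_equal(ev[1], 1, tolerance = 1e-10)  # rank-1 construction
})

test_that("pcaScreen handles duplicate data and bad ranks", {
  X <- matrix(rep(c(0.1, 0.4, 0.9), each = 4), 4, 3, byrow = FALSE)
  X <- rbind(X, X[1, ] + c(0.2, 0, 0))  # variation along one axis only
  s <- SpectrumSet(X, 850:852)
  res <- pcaScreen(s, nComponents = 2)
  expect_equal(attr(res, "explainedVariance")[2], 0, tolerance = 1e-12)
  expect_error(pcaScreen(s, nComponents = 5), "below the sample count")
  expect_error(pcaScreen(s[1:2], 1), "at least 3")
})

test_that("rank-1 Beer-Lambert data is fit exactly with one latent variable", {
  set.seed(22)
  band <- exp(-0.5 * ((grid - 1045) / 12)^2)
  y <- runif(12, 2, 10)
  s <- SpectrumSet(outer(y, band), grid)
  m <- fitPLS(s, y, nLV = 1)
  expect_equal(unname(m@fittedValues), y, tolerance = 1e-8)
  expect_equal(unname(predict(m, s)), y, tolerance = 1e-8)
})

test_that("NIPALS at full rank equals the minimum-norm least-squares oracle", {
  set.seed(23)
  X <- matrix(rnorm(10 * 20), 10, 20)
  y <- rnorm(10)
  m <- fitPLS(X, y, nLV = 9)   # rank of the centred 10 x 20 block
  expect_equal(unname(m@fittedValues), lsOracle(X, y), tolerance = 1e-6)

  # and on new data the collapsed affine map agrees with the oracle
  Xnew <- matrix(rnorm(5 * 20), 5, 20)
  expect_equal(unname(predict(m, Xnew)), lsOracle(X, y, Xnew),
               tolerance = 1e-6)
})

test_that("NIPALS scores are mutually orthogonal and the fit is deterministic", {
  set.seed(24)
  sim <- simulateDataset(SimConfig(seed = 31))
  cal <- averageReplicates(sim$spectra)
  y <- sim$design$ethanol
  m <- fitPLS(cal, y, 6, buildPipeline("sub_min+2nd_derivative"))
  G <- crossprod(m@scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)

  # permuting sample order leaves the regression vector unchanged
  perm <- sample(length(cal))
  m2 <- fitPLS(cal[perm], y[perm], 6, buildPipeline("sub_min+2nd_derivative"))
  expect_equal(m2@coefficients, m@coefficients, tolerance = 1e-10)
  expect_equal(m2@intercept, m@intercept, tolerance = 1e-10)

  m3 <- fitPLS(cal, y, 6, buildPipeline("sub_min+2nd_derivative"))
  expect_identical(m3@coefficients, m@coefficients)
})

test_that("fitPLS validates rank, response variance and grid compatibility", {
  set.seed(25)
  X <- matrix(rnorm(6 * 10), 6, 10)
  expect_error(fitPLS(X, rnorm(6), nLV = 6), "exceed")
  expect_error(fitPLS(X, rep(1, 6), nLV = 2), "zero variance")
  # duplicated rows cap the usable rank below the requested count
  Xdup <- X[rep(1:2, 3), ]
  expect_error(fitPLS(Xdup, rnorm(6), nLV = 4), "rank")

  sim <- simulateDataset(SimConfig(nStandards = 6, seed = 5))
  cal <- averageReplicates(sim$spectra)
  m <- fitPLS(cal, sim$design$ethanol, 2)
  off <- SpectrumSet(absorbance(cal), wavenumbers(cal) + 5)
  expect_error(predict(m, off), "training grid")
})

test_that("predicting the training set reproduces fit-time values; duplicates agree", {
  sim <- simulateDataset(SimConfig(nStandards = 10, seed = 6))
  cal <- averageReplicates(sim$spectra)
  y <- sim$design$ethanol
  m <- fitPLS(cal, y, 4, buildPipeline("sub_min+2nd_derivative+mean_centering"))
  expect_equal(predict(m, cal), m@fittedValues)
  # identical spectra must get identical predictions
  dup <- SpectrumSet(rbind(absorbance(cal)[1, ], absorbance(cal)[1, ]),
                     wavenumbers(cal), sampleIds = c("d1", "d2"))
  p <- predict(m, dup)
  expect_equal(unname(p[1]), unname(p[2]))
})

test_that("looCV equals the naive per-fold re-implementation and fits n models", {
  sim <- simulateDataset(SimConfig(nStandards = 12, seed = 8))
  cal <- averageReplicates(sim$spectra)
  y <- sim$design$ethanol
  mm <- looCV(cal, y, buildPipeline("sub_min+2nd_derivative"), nLV = 4)
  expect_length(mm@cvPredictions, 12L)
  expect_equal(mm@rmsecv, naiveLoo(cal, y, "sub_min+2nd_derivative", 4),
               tolerance = 1e-12)
  # secv/sec are the dof-corrected analogues
  expect_gt(mm@secv, mm@rmsecv)
  expect_gt(mm@sec, mm@rmsee)
})

test_that("looCV is exact on noiseless rank-deficient data", {
  set.seed(26)
  band <- exp(-0.5 * ((grid - 1045) / 12)^2)
  y <- runif(10, 2, 10)
  s <- SpectrumSet(outer(y, band), grid)
  mm <- looCV(s, y, nLV = 1)
  expect_lt(mm@rmsecv, 1e-6)
})

test_that("looCV names the failing fold when a fold cannot be fitted", {
  # 4 samples, two identical pairs: dropping one sample leaves rank 2
  # centred rank 1, so 3 components cannot be extracted in any fold
  X <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0) + 1e-9,
             c(0, 0, 1, 0))
  expect_error(looCV(X, c(1, 2, 1.1, 3), nLV = 3), "fold 1")
})

test_that("selectNLV applies the parsimony rule", {
  # data generated from exactly 2 latent factors at low noise
  set.seed(27)
  n <- 20
  f1 <- exp(-0.5 * ((grid - 1045) / 15)^2)
  f2 <- exp(-0.5 * ((grid - 980) / 20)^2)
  c1 <- runif(n, 2, 10); c2 <- runif(n, 0, 5)
  X <- outer(c1, f1) + outer(c2, f2) +
    matrix(rnorm(n * 351, 0, 1e-5), n)
  y <- c1
  sel <- selectNLV(SpectrumSet(X, grid), y, maxLV = 8)
  expect_identical(sel$nLV, 2L)
  expect_length(sel$rmsecvCurve, 8L)

  expect_identical(selectNLV(SpectrumSet(X, grid), y, maxLV = 1)$nLV, 1L)

  # parsimony contract: the chosen count is the first within the margin
  # of the minimum, and nothing smaller qualifies
  sim <- simulateDataset(SimConfig(seed = 9))
  cal <- averageReplicates(sim$spectra)
  s2 <- selectNLV(cal, sim$design$ethanol,
                  buildPipeline("sub_min+2nd_derivative"), maxLV = 10)
  crv <- s2$rmsecvCurve
  expect_lte(crv[s2$nLV], min(crv) + s2$margin)
  if (s2$nLV > 1)
    expect_true(all(crv[seq_len(s2$nLV - 1)] > min(crv) + s2$margin))
  expect_gte(s2$margin, 0.02 * min(crv))
})

test_that("comparePretreatments ranks by validation performance", {
  simCal <- simulateDataset(SimConfig(seed = 12))
  simVal <- simulateDataset(SimConfig(nStandards = 10, seed = 13))
  cal <- averageReplicates(simCal$spectra)
  val <- averageReplicates(simVal$spectra)
  tab <- comparePretreatments(cal, simCal$design$ethanol,
                              val, simVal$design$ethanol,
                              c("raw", "sub_min+2nd_derivative",
                                "sub_min+mean_centering"), maxLV = 8)
  expect_identical(nrow(tab), 3L)
  expect_false(any(tab$failed))
  # the winner's ranking key dominates: no later row may beat it
  expect_true(all(tab$r2Pred[1] >= tab$r2Pred - 1e-9))

  one <- comparePretreatments(cal, simCal$design$ethanol,
                              val, simVal$design$ethanol, "raw", maxLV = 4)
  expect_identical(nrow(one), 1L)
  expect_error(comparePretreatments(cal, simCal$design$ethanol, val,
                                    simVal$design$ethanol, "nope"),
               "unknown pipeline")
})

test_that("derivative pipelines beat normalization pipelines under baseline drift", {
  # injected polynomial baseline (0.02 AU) defeats chains that lack a
  # derivative; majority vote over 10 seeds
  wins <- 0L
  for (seed in 1:10) {
    cfg <- SimConfig(baselineAmplitude = 0.02, seed = seed)
    simCal <- simulateDataset(cfg)
    simVal <- simulateDataset(SimConfig(nStandards = 10,
                                        baselineAmplitude = 0.02,
                                        seed = seed + 100))
    tab <- comparePretreatments(
      averageReplicates(simCal$spectra), simCal$design$ethanol,
      averageReplicates(simVal$spectra), simVal$design$ethanol,
      c("sub_min+2nd_derivative", "sub_min+normalization+mean_centering"),
      maxLV = 8)
    if (tab$pipeline[1] == "sub_min+2nd_derivative") wins <- wins + 1L
  }
  expect_gt(wins, 5L)
})

test_that("PLS models survive a JSON round-trip", {
  sim <- simulateDataset(SimConfig(nStandards = 10, seed = 14))
  cal <- averageReplicates(sim$spectra)
  m <- fitPLS(cal, sim$design$ethanol, 3,
              buildPipeline("sub_min+2nd_derivative+mean_centering"))
  f <- withr::local_tempfile(fileext = ".json")
  writePLSModel(m, f)
  m2 <- readPLSModel(f)
  expect_equal(predict(m2, cal), predict(m, cal), tolerance = 1e-12)
  expect_identical(m2@nLV, m@nLV)
  expect_identical(m2@pipeline@name, m@pipeline@name)
})

test_that("NIPALS predictions agree with an established PLS implementation", {
  suppressMessages(requireNamespace("mixOmics"))
  set.seed(28)
  X <- matrix(rnorm(15 * 30), 15, 30,
              dimnames = list(NULL, paste0("v", 1:30)))
  y <- rnorm(15)
  m <- fitPLS(X, y, 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, scale = FALSE, mode = "regression")
  refPred <- predict(ref, X)$predict[, 1, 4]
  expect_equal(unname(m@fittedValues), unname(refPred), tolerance = 1e-8)
})
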