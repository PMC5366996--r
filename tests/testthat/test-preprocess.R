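grid <- seq(850, 1200, by = 1)

test_that("subtractMinimum zeroes each spectrum's minimum and is idempotent", {
  s <- SpectrumSet(rbind(rep(0.7, 5), c(0.3, 0.1, 0.5, 0.2, 0.9)),
                   850:854)
  r <- subtractMinimum(s)
  expect_equal(as.numeric(absorbance(r)[1, ]), rep(0, 5))
  expect_equal(as.numeric(absorbance(r)[2, ]), c(0.2, 0.0, 0.4, 0.1, 0.8))
  expect_equal(absorbance(subtractMinimum(r)), absorbance(r))
  expect_equal(apply(absorbance(subtractMinimum(makeRandomSet(4, grid))),
                     1, min), rep(0, 4), ignore_attr = TRUE)
})

test_that("min-max normalization maps to [0,1], is idempotent, rejects flat spectra", {
  s <- SpectrumSet(matrix(c(0, 2, 4), 1), 850:852)
  r <- normalizeSpectra(s)
  expect_equal(as.numeric(absorbance(r)), c(0, 0.5, 1))
  expect_equal(absorbance(normalizeSpectra(r)), absorbance(r))
  flat <- SpectrumSet(matrix(0.7, 1, 3), 850:852, sampleIds = "flat1")
  expect_error(normalizeSpectra(flat), "flat.*flat1")

  # alternative normalizations keep their defining property
  v <- normalizeSpectra(makeRandomSet(3, grid), method = "vector")
  expect_equal(sqrt(rowSums(absorbance(v)^2)), rep(1, 3),
               ignore_attr = TRUE)
  a <- normalizeSpectra(makeRandomSet(3, grid), method = "area")
  expect_equal(rowSums(absorbance(a)) * 1, rep(1, 3), ignore_attr = TRUE)
})

test_that("derivatives reproduce polynomials exactly", {
  nu <- grid
  lin <- SpectrumSet(matrix(2 + 0.003 * nu, 1), nu)
  d1 <- spectralDerivative(lin, 1)
  expect_equal(as.numeric(absorbance(d1)), rep(0.003, 351),
               tolerance = 1e-9)
  quad <- SpectrumSet(matrix(4e-5 * nu^2, 1), nu)
  d2 <- spectralDerivative(quad, 2)
  expect_equal(as.numeric(absorbance(d2)), rep(8e-5, 351),
               tolerance = 1e-9)
})

test_that("derivative matches the brute-force windowed polyfit oracle", {
  g51 <- seq(1000, 1050, by = 1)
  set.seed(7)
  x <- runif(51)
  s <- SpectrumSet(matrix(x, 1), g51)
  got <- as.numeric(absorbance(spectralDerivative(s, 1, window = 5,
                                                  polyorder = 2)))
  expect_equal(got, sgOracle(x, g51, 1, 5, 2), tolerance = 1e-9)
  got2 <- as.numeric(absorbance(spectralDerivative(s, 2, window = 9,
                                                   polyorder = 3)))
  expect_equal(got2, sgOracle(x, g51, 2, 9, 3), tolerance = 1e-9)

  # spacing scaling: same shape on a 2 cm-1 grid halves the derivative
  g2 <- seq(1000, 1100, by = 2)
  s2 <- SpectrumSet(matrix(x, 1), g2)
  got3 <- as.numeric(absorbance(spectralDerivative(s2, 1, window = 5,
                                                   polyorder = 2)))
  expect_equal(got3, got / 2, tolerance = 1e-9)
})

test_that("derivative is linear and validates its arguments", {
  set.seed(8)
  x <- makeRandomSet(1, grid, seed = 1)
  y <- makeRandomSet(1, grid, seed = 2)
  lhs <- SpectrumSet(3 * absorbance(x) - 2 * absorbance(y), grid)
  d <- function(s) absorbance(spectralDerivative(s, 1))
  expect_equal(d(lhs), 3 * d(x) - 2 * d(y), tolerance = 1e-9,
               ignore_attr = TRUE)

  short <- makeRandomSet(1, 850:856)
  expect_error(spectralDerivative(short, 1, window = 7), "shorter")
  expect_error(spectralDerivative(x, 3), "order")
  expect_error(spectralDerivative(x, 1, window = 8), "odd")
  expect_error(spectralDerivative(x, 2, polyorder = 1), "polyorder")
})

test_that("meanCenter zeroes fitted columns and reuses stored means", {
  s <- makeRandomSet(6, grid, seed = 4)
  c1 <- meanCenter(s)
  expect_equal(colMeans(absorbance(c1)), rep(0, 351),
               tolerance = 1e-12, ignore_attr = TRUE)

  # two identical samples centre to zero vectors
  twin <- SpectrumSet(rbind(absorbance(s)[1, ], absorbance(s)[1, ]), grid)
  expect_equal(max(abs(absorbance(meanCenter(twin)))), 0)

  # a new spectrum is centred with the stored means, not its own
  mu <- colMeans(absorbance(s))
  new1 <- makeRandomSet(1, grid, seed = 9)
  expect_equal(absorbance(meanCenter(new1, mu)),
               absorbance(new1) - rep(mu, each = 1), ignore_attr = TRUE)
  expect_error(meanCenter(new1), "at least 2 samples")
})

test_that("the pipeline registry covers the eleven chains plus raw", {
  nms <- pipelineNames()
  expect_length(nms, 12L)
  expect_true("raw" %in% nms)

  p <- buildPipeline("sub_min+2nd_derivative")
  expect_identical(vapply(p@steps, `[[`, "", "op"),
                   c("subtract_minimum", "derivative"))
  expect_identical(p@steps[[2]]$order, 2L)

  p4 <- buildPipeline("sub_min+normalization+1st_derivative+mean_centering")
  expect_identical(vapply(p4@steps, `[[`, "", "op"),
                   c("subtract_minimum", "normalize", "derivative",
                     "mean_center"))
  expect_identical(p4@steps[[3]]$order, 1L)

  expect_length(buildPipeline("raw")@steps, 0L)
  expect_error(buildPipeline("snv"), "valid names")
})

test_that("raw pipeline is the identity and fitted state is reused verbatim", {
  s <- makeRandomSet(5, grid, seed = 10)
  raw <- fitPipeline(buildPipeline("raw"), s)
  expect_equal(absorbance(applyPipeline(raw, s)), absorbance(s))

  p <- fitPipeline(
    buildPipeline("sub_min+normalization+2nd_derivative+mean_centering"), s)
  t1 <- applyPipeline(p, s)
  t2 <- applyPipeline(p, s)
  expect_identical(absorbance(t1), absorbance(t2))  # bit-for-bit

  # a single new spectrum goes through stored means (own centring would
  # send it to zero)
  one <- s[1]
  tr <- applyPipeline(p, one)
  expect_gt(max(abs(absorbance(tr))), 0)

  unfitted <- buildPipeline("sub_min+mean_centering")
  expect_error(applyPipeline(unfitted, s), "has not been fitted")
})

test_that("pipeline configs load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines("pipeline: sub_min+2nd_derivative\nwindow: 11", fy)
  p <- readPipelineConfig(fy)
  expect_identical(p@name, "sub_min+2nd_derivative")
  expect_identical(p@steps[[2]]$window, 11L)

  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"custom","steps":[{"op":"subtract_minimum"},{"op":"derivative","order":1,"window":9,"polyorder":2}]}', fj)
  pj <- readPipelineConfig(fj)
  expect_identical(vapply(pj@steps, `[[`, "", "op"),
                   c("subtract_minimum", "derivative"))
})
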