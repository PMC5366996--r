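#' @include spectra-io.R
NULL

#' SimConfig: settings of the synthetic-spectrum simulator
#'
#' Defaults reproduce the calibration design the package targets: 25
#' five-component standards on the 1200-850 cm-1 grid at 1 cm-1 spacing
#' (351 points), recorded in triplicate with white instrument noise of
#' 5e-4 AU and no baseline drift.
#'
#' @slot nStandards standards in the design (>= 3)
#' @slot gridLow,gridHigh,gridStep wavenumber window and spacing (cm-1)
#' @slot noiseSigma instrument noise standard deviation (AU, >= 0)
#' @slot baselineAmplitude amplitude of a random per-spectrum quadratic
#'   baseline drift (AU; 0 disables it)
#' @slot replicateCount instrument replicates per standard
#' @slot seed RNG seed; every random draw of the simulator flows from it
#' @export
setClass("SimConfig",
  representation(
    nStandards        = "integer",
    gridLow           = "numeric",
    gridHigh          = "numeric",
    gridStep          = "numeric",
    noiseSigma        = "numeric",
    baselineAmplitude = "numeric",
    replicateCount    = "integer",
    seed              = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nStandards < 3L) return("nStandards must be >= 3")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@replicateCount < 1L) return("replicateCount must be >= 1")
  if (object@gridLow >= object@gridHigh) return("gridLow must be < gridHigh")
  TRUE
})

#' @rdname SimConfig-class
#' @param nStandards,gridLow,gridHigh,gridStep,noiseSigma,baselineAmplitude,replicateCount,seed
#'   see the class slots
#' @return a [SimConfig-class]
#' @examples
#' SimConfig()               # the default 25-standard design
#' SimConfig(noiseSigma = 5e-2, seed = 7)
#' @export
SimConfig <- function(nStandards = 25L, gridLow = 850, gridHigh = 1200,
                      gridStep = 1, noiseSigma = 5e-4,
                      baselineAmplitude = 0, replicateCount = 3L,
                      seed = 42L) {
  new("SimConfig", nStandards = as.integer(nStandards),
      gridLow = gridLow, gridHigh = gridHigh, gridStep = gridStep,
      noiseSigma = noiseSigma, baselineAmplitude = baselineAmplitude,
      replicateCount = as.integer(replicateCount), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d standards x %d replicates, %g-%g cm-1 step %g,\n  noise %g AU, baseline %g AU, seed %d\n",
    object@nStandards, object@replicateCount, object@gridLow,
    object@gridHigh, object@gridStep, object@noiseSigma,
    object@baselineAmplitude, object@seed))
})

.COMPONENTS <- c("ethanol", "glucose", "fructose", "sucrose", "maltose")

## concentration ranges (% w/w) of the calibration design
.DESIGN_RANGES <- list(
  ethanol = c(2, 10), glucose = c(0, 5), fructose = c(0, 5),
  sucrose = c(0, 5), maltose = c(0, 5))

#' Default Gaussian band model of the five mixture components
#'
#' Per component, a set of Gaussian bands `(center cm-1, width cm-1,
#' amplitude AU per % w/w)` inside the 1200-850 cm-1 working window.
#' Band locations follow the known mid-IR picture - ethanol's C-O
#' stretches near 1087 and 1045 cm-1 and the weaker band near 880 cm-1,
#' sugar C-O/C-C bands crowding 950-1150 cm-1 and overlapping the ethanol
#' bands - but widths and absorptivities are synthetic fixtures chosen to
#' give realistic ATR absorbance scales (strongest ethanol band about
#' 0.25 AU at 10 % w/w). The sugar-ethanol overlap is deliberate: it is
#' what makes multivariate calibration necessary.
#'
#' @return named list (one entry per component) of `data.frame`s with
#'   columns `center`, `width`, `amplitude`
#' @export
defaultBandModel <- function() {
  b <- function(...) {
    m <- rbind(...)
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  list(
    ethanol  = b(c(1045, 12, 0.025), c(1087, 16, 0.016), c(880, 9, 0.008)),
    glucose  = b(c(1035, 20, 0.012), c(1080, 22, 0.009), c(992, 15, 0.007)),
    fructose = b(c(1063, 18, 0.011), c(980, 16, 0.008)),
    sucrose  = b(c(995, 16, 0.012), c(1055, 20, 0.009), c(925, 14, 0.005)),
    maltose  = b(c(1030, 20, 0.011), c(1150, 18, 0.006), c(900, 12, 0.004))
  )
}

.checkBandModel <- function(bandModel) {
  for (nm in names(bandModel)) {
    bm <- bandModel[[nm]]
    if (!all(c("center", "width", "amplitude") %in% names(bm)))
      stop("band model entry '", nm,
           "' needs center, width and amplitude columns")
    if (any(bm$amplitude <= 0) || any(bm$width <= 0))
      stop("band model entry '", nm,
           "' has non-positive width or amplitude")
  }
  invisible(bandModel)
}

#' Read / write a band model as YAML
#'
#' @param path YAML file; a mapping of component name to a list of bands,
#'   each with `center`, `width`, `amplitude`
#' @return [readBandModel()]: a band model list; [writeBandModel()]:
#'   `path`, invisibly
#' @export
readBandModel <- function(path) {
  raw <- yaml::read_yaml(path)
  bm <- lapply(raw, function(comp) {
    do.call(rbind, lapply(comp, function(band)
      data.frame(center = band$center, width = band$width,
                 amplitude = band$amplitude)))
  })
  .checkBandModel(bm)
}

#' @rdname readBandModel
#' @param bandModel a band model list (see [defaultBandModel()])
#' @export
writeBandModel <- function(bandModel, path) {
  .checkBandModel(bandModel)
  out <- lapply(bandModel, function(bm)
    lapply(seq_len(nrow(bm)), function(i)
      list(center = bm$center[i], width = bm$width[i],
           amplitude = bm$amplitude[i])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Draw a random calibration design
#'
#' Independent uniform draws per component within the calibration ranges
#' (ethanol 2-10 % w/w, each sugar 0-5 % w/w), so component concentrations
#' are uncorrelated by construction. A Latin hypercube variant
#' (`method = "lhs"`, space-filling marginals, still uncorrelated) is
#' available when the `lhs` package is installed.
#'
#' @param config a [SimConfig-class] (its `nStandards` and `seed` are used)
#' @param method `"uniform"` (default) or `"lhs"`
#' @return `data.frame` of the five concentrations, one row per standard,
#'   with attribute `pairwiseCorrelations` (the sample correlation matrix)
#' @export
generateDesign <- function(config = SimConfig(),
                           method = c("uniform", "lhs")) {
  method <- match.arg(method)
  n <- config@nStandards
  set.seed(config@seed)
  u <- if (method == "lhs") {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("generateDesign: method 'lhs' needs the lhs package")
    lhs::randomLHS(n, length(.COMPONENTS))
  } else {
    matrix(stats::runif(n * length(.COMPONENTS)), n)
  }
  design <- as.data.frame(mapply(function(uk, rng)
    rng[1] + uk * (rng[2] - rng[1]),
    asplit(u, 2), .DESIGN_RANGES[.COMPONENTS]))
  names(design) <- .COMPONENTS
  rownames(design) <- sprintf("std%02d", seq_len(n))
  attr(design, "pairwiseCorrelations") <- stats::cor(design)
  design
}

#' Pure-component spectrum at 1 % w/w
#'
#' Sum of the component's Gaussian bands evaluated on the grid.
#'
#' @param component one of `ethanol`, `glucose`, `fructose`, `sucrose`,
#'   `maltose` (or any name present in `bandModel`)
#' @param grid wavenumber grid (cm-1)
#' @param bandModel see [defaultBandModel()]
#' @return numeric absorbance vector (AU per % w/w) on `grid`
#' @export
pureComponentSpectrum <- function(component, grid = seq(850, 1200, by = 1),
                                  bandModel = defaultBandModel()) {
  if (!component %in% names(bandModel))
    stop("unknown component '", component, "'; band model defines: ",
         paste(names(bandModel), collapse = ", "))
  bm <- bandModel[[component]]
  rowSums(vapply(seq_len(nrow(bm)), function(i)
    bm$amplitude[i] * exp(-0.5 * ((grid - bm$center[i]) / bm$width[i])^2),
    numeric(length(grid))))
}

#' Simulate a calibration data set of mixture spectra
#'
#' Beer-Lambert additive mixtures: each standard's noiseless spectrum is
#' the concentration-weighted sum of the pure-component spectra; each
#' replicate adds i.i.d. Gaussian instrument noise (and, when
#' `baselineAmplitude > 0`, a random quadratic baseline drift shared by no
#' one else). Absorbance is floored at zero, as measured absorbance of
#' these non-absorbing-free mixtures cannot go negative. All randomness
#' flows from `config@seed`, so equal seeds give bit-identical data sets.
#'
#' @param config a [SimConfig-class]
#' @param bandModel see [defaultBandModel()]
#' @param design optional pre-built design `data.frame` (defaults to
#'   [generateDesign()] under the same config)
#' @return list with `spectra` (a [SpectrumSet-class] of
#'   `nStandards * replicateCount` spectra, replicate mapping set) and
#'   `design` (the composition table)
#' @examples
#' sim <- simulateDataset(SimConfig(seed = 42))
#' sim$spectra
#' @export
simulateDataset <- function(config = SimConfig(),
                            bandModel = defaultBandModel(),
                            design = NULL) {
  .checkBandModel(bandModel)
  grid <- seq(config@gridLow, config@gridHigh, by = config@gridStep)
  if (is.null(design)) design <- generateDesign(config)
  comps <- intersect(names(design), names(bandModel))
  pure <- vapply(comps, pureComponentSpectrum, numeric(length(grid)),
                 grid = grid, bandModel = bandModel)
  clean <- as.matrix(design[, comps, drop = FALSE]) %*% t(pure)

  set.seed(config@seed + 1L)   # distinct stream from the design draw
  n <- nrow(design); r <- config@replicateCount
  a <- matrix(NA_real_, n * r, length(grid))
  ids <- character(n * r)
  parent <- character(n * r)
  u <- (grid - min(grid)) / (max(grid) - min(grid))
  row <- 0L
  for (i in seq_len(n)) {
    for (k in seq_len(r)) {
      row <- row + 1L
      drift <- if (config@baselineAmplitude > 0) {
        cf <- stats::runif(3, -1, 1) * config@baselineAmplitude
        cf[1] + cf[2] * u + cf[3] * u^2
      } else 0
      noise <- if (config@noiseSigma > 0)
        stats::rnorm(length(grid), 0, config@noiseSigma) else 0
      a[row, ] <- pmax(clean[i, ] + drift + noise, 0)
      ids[row] <- sprintf("%s_r%d", rownames(design)[i], k)
      parent[row] <- rownames(design)[i]
    }
  }
  list(spectra = SpectrumSet(a, grid, sampleIds = ids,
                             replicateOf = parent),
       design = design)
}

#' Simulate internal-standard GC-FID peak-area ratios
#'
#' Generates area ratios from a calibration line plus Gaussian noise:
#' `ratio = slope * conc + intercept + N(0, noiseSigma)`.
#'
#' @param concentration ethanol concentrations (% w/w)
#' @param curve a [CalibrationCurve-class] acting as the generating truth
#' @param noiseSigma area-ratio noise standard deviation
#' @param seed RNG seed
#' @return numeric vector of simulated area ratios
#' @export
simulateGCAreas <- function(concentration, curve, noiseSigma = 0,
                            seed = 42L) {
  set.seed(as.integer(seed))
  curve@slope * concentration + curve@intercept +
    if (noiseSigma > 0) stats::rnorm(length(concentration), 0, noiseSigma)
    else 0
}

#' Build a CalibrationCurve from known coefficients
#'
#' Convenience constructor for using a published line (e.g. as the
#' generating truth of [simulateGCAreas()]) without refitting it.
#'
#' @param slope,intercept line coefficients (area-ratio vs % w/w)
#' @param r2 coefficient of determination to record (default `NA`)
#' @param residualSigma residual standard deviation (default 0)
#' @param nPoints points behind the line (default 0 = unknown)
#' @return a [CalibrationCurve-class]
#' @examples
#' referenceCurve <- makeCalibrationCurve(0.13903, 0.04488, r2 = 0.9992)
#' @export
makeCalibrationCurve <- function(slope, intercept, r2 = NA_real_,
                                 residualSigma = 0, nPoints = 0L) {
  new("CalibrationCurve", slope = slope, intercept = intercept, r2 = r2,
      residualSigma = residualSigma,
      lod = 3 * residualSigma / abs(slope),
      loq = 10 * residualSigma / abs(slope),
      nPoints = as.integer(nPoints))
}
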