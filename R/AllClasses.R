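#' @include AllGenerics.R
NULL

## relative tolerance for grid-uniformity checks; derivative filters assume
## constant spacing
.GRID_RTOL <- 1e-6

.checkGrid <- function(grid) {
  if (length(grid) < 2L) return(NULL)
  d <- diff(grid)
  if (any(d <= 0)) return("wavenumber grid must be strictly increasing")
  if (max(abs(d - d[1])) > .GRID_RTOL * abs(d[1]))
    return(sprintf(
      "wavenumber grid is not uniformly spaced (max deviation %.3g cm-1)",
      max(abs(d - d[1]))))
  NULL
}

#' SpectrumSet: absorbance spectra on a common wavenumber grid
#'
#' The X-block of the calibration problem: one absorbance spectrum per
#' sample, all on the same strictly increasing, uniformly spaced wavenumber
#' grid. The canonical working window is 1200-850 cm-1 at 1 cm-1 spacing
#' (351 points). An optional replicate mapping records which spectra are
#' instrument replicates of the same physical sample.
#'
#' @slot wavenumbers numeric, strictly increasing, uniform spacing
#' @slot absorbance numeric matrix, samples x grid points, absorbance units
#' @slot sampleIds character, unique, one per row
#' @slot replicateOf character, parent-sample label per row (length 0 when
#'   the set has no replicate structure)
#'
#' @seealso [SpectrumSet()], [readSpectraCSV()], [selectRegion()],
#'   [averageReplicates()]
#' @export
setClass("SpectrumSet",
  representation(
    wavenumbers = "numeric",
    absorbance  = "matrix",
    sampleIds   = "character",
    replicateOf = "character"
  )
)

setValidity("SpectrumSet", function(object) {
  msgs <- character()
  g <- object@wavenumbers
  a <- object@absorbance
  if (ncol(a) != length(g))
    msgs <- c(msgs, sprintf("absorbance has %d columns but grid has %d points",
                            ncol(a), length(g)))
  gerr <- .checkGrid(g)
  if (!is.null(gerr)) msgs <- c(msgs, gerr)
  if (length(object@sampleIds) != nrow(a))
    msgs <- c(msgs, "one sample id per spectrum required")
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, sprintf("duplicate sample id(s): %s",
      paste(unique(object@sampleIds[duplicated(object@sampleIds)]),
            collapse = ", ")))
  if (!all(is.finite(a)))
    msgs <- c(msgs, "absorbance values must all be finite")
  if (length(object@replicateOf) &&
      length(object@replicateOf) != nrow(a))
    msgs <- c(msgs, "replicateOf must map every spectrum or be absent")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumSet
#'
#' Descending grids are accepted and reversed (together with the absorbance
#' columns) to the canonical ascending orientation.
#'
#' @param absorbance numeric matrix, samples in rows
#' @param wavenumbers numeric grid (cm-1), ascending or descending
#' @param sampleIds unique sample labels; defaults to rownames or `s1..sn`
#' @param replicateOf optional parent-sample label per spectrum
#' @return a validated [SpectrumSet-class]
#' @examples
#' grid <- seq(850, 1200, by = 1)
#' a <- matrix(rexp(2 * length(grid), 10), nrow = 2)
#' SpectrumSet(a, grid, sampleIds = c("std1", "std2"))
#' @export
SpectrumSet <- function(absorbance, wavenumbers,
                        sampleIds = NULL, replicateOf = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) > 1L && wavenumbers[1] > wavenumbers[2]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  if (is.null(sampleIds))
    sampleIds <- rownames(absorbance)
  if (is.null(sampleIds))
    sampleIds <- paste0("s", seq_len(nrow(absorbance)))
  rownames(absorbance) <- sampleIds
  new("SpectrumSet",
      wavenumbers = wavenumbers,
      absorbance  = absorbance,
      sampleIds   = as.character(sampleIds),
      replicateOf = if (is.null(replicateOf)) character(0)
                    else as.character(replicateOf))
}

#' PretreatmentPipeline: an ordered chain of spectral pre-treatments
#'
#' Holds the ordered operator descriptors of one pre-treatment chain
#' (drawn from minimum subtraction, min-max normalization, Savitzky-Golay
#' derivative, mean centering) plus, after [fitPipeline()], the
#' data-dependent state (column means) learned on the calibration set.
#' Applying a fitted pipeline to new spectra always reuses the stored
#' state.
#'
#' @slot name the chain's registry name (see [pipelineNames()])
#' @slot steps list of step descriptors, each `list(op = ..., ...)`
#' @slot fitted logical, `TRUE` once data-dependent state has been learned
#' @slot state per-step learned parameters (e.g. `columnMeans`)
#' @seealso [buildPipeline()], [fitPipeline()], [applyPipeline()]
#' @export
setClass("PretreatmentPipeline",
  representation(
    name   = "character",
    steps  = "list",
    fitted = "logical",
    state  = "list"
  ),
  prototype(fitted = FALSE, state = list())
)

.PIPELINE_OPS <- c("subtract_minimum", "normalize", "derivative",
                   "mean_center")

setValidity("PretreatmentPipeline", function(object) {
  ops <- vapply(object@steps, function(s) s$op %||% "", "")
  bad <- setdiff(ops, .PIPELINE_OPS)
  if (length(bad))
    sprintf("unsupported pipeline step(s): %s", paste(bad, collapse = ", "))
  else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PLSModel: a fitted PLS1 latent-variable calibration model
#'
#' The result of [fitPLS()]: NIPALS weights, loadings and scores for
#' `nLV` latent variables, the centering offsets, and the collapsed
#' regression vector so that prediction is a single affine map of a
#' pre-treated spectrum. When fitted through a pipeline the model carries
#' the fitted [PretreatmentPipeline-class] and the training grid, and
#' [predict()] applies both.
#'
#' @slot nLV number of latent variables (PLS components)
#' @slot weights p x nLV NIPALS weight vectors
#' @slot xLoadings p x nLV X-block loadings
#' @slot yLoadings length-nLV y loadings
#' @slot scores n x nLV orthogonal score vectors (training set)
#' @slot xMean,yMean centering offsets
#' @slot coefficients length-p regression vector on pre-treated spectra
#' @slot intercept scalar intercept of the collapsed affine map
#' @slot fittedValues training-set predictions (% w/w)
#' @slot grid training wavenumber grid (length 0 for bare-matrix fits)
#' @slot pipeline fitted pre-treatment pipeline used at training time
#' @export
setClass("PLSModel",
  representation(
    nLV          = "integer",
    weights      = "matrix",
    xLoadings    = "matrix",
    yLoadings    = "numeric",
    scores       = "matrix",
    xMean        = "numeric",
    yMean        = "numeric",
    coefficients = "numeric",
    intercept    = "numeric",
    fittedValues = "numeric",
    grid         = "numeric",
    pipeline     = "PretreatmentPipeline"
  )
)

setValidity("PLSModel", function(object) {
  if (object@nLV < 1L)
    return("a PLS model needs at least one latent variable")
  if (ncol(object@weights) != object@nLV)
    return("weights must hold one column per latent variable")
  TRUE
})

#' ModelMetrics: error and determination record of one calibration model
#'
#' Collects the figures of merit reported for a PLS calibration:
#' root-mean-square errors of estimation (`rmsee`, calibration fit),
#' cross-validation (`rmsecv`, leave-one-out) and prediction (`rmsep`,
#' external validation set), their degrees-of-freedom-corrected analogues
#' (`sec`, `secv`, `sep`, denominator n - nLV - 1), and the coefficients of
#' determination (`r2Cal`, `r2Cval`, `r2Pred`). Quantities not computed in a
#' given context are `NA`.
#'
#' @slot nLV latent variables used
#' @slot rmsee,sec,r2Cal calibration-set figures (% w/w for errors)
#' @slot rmsecv,secv,r2Cval leave-one-out cross-validation figures
#' @slot rmsep,sep,r2Pred external-validation figures
#' @slot cvPredictions per-sample out-of-fold predictions (named, % w/w)
#' @export
setClass("ModelMetrics",
  representation(
    nLV           = "integer",
    rmsee         = "numeric",
    sec           = "numeric",
    r2Cal         = "numeric",
    rmsecv        = "numeric",
    secv          = "numeric",
    r2Cval        = "numeric",
    rmsep         = "numeric",
    sep           = "numeric",
    r2Pred        = "numeric",
    cvPredictions = "numeric"
  ),
  prototype(rmsee = NA_real_, sec = NA_real_, r2Cal = NA_real_,
            rmsecv = NA_real_, secv = NA_real_, r2Cval = NA_real_,
            rmsep = NA_real_, sep = NA_real_, r2Pred = NA_real_,
            cvPredictions = numeric(0))
)

setValidity("ModelMetrics", function(object) {
  errs <- c(object@rmsee, object@sec, object@rmsecv, object@secv,
            object@rmsep, object@sep)
  r2s <- c(object@r2Cal, object@r2Cval, object@r2Pred)
  if (any(errs < 0, na.rm = TRUE)) return("error metrics must be >= 0")
  if (any(r2s > 1 + 1e-12, na.rm = TRUE)) return("R-squared cannot exceed 1")
  TRUE
})

#' CalibrationCurve: internal-standard GC-FID calibration line
#'
#' An ordinary least-squares line of ethanol:n-propanol peak-area ratio
#' against ethanol concentration (% w/w), with the residual standard
#' deviation (n - 2 degrees of freedom) from which the detection and
#' quantification limits follow as 3 sigma / |slope| and 10 sigma / |slope|.
#'
#' @slot slope area-ratio per % w/w
#' @slot intercept area-ratio at zero concentration
#' @slot r2 coefficient of determination of the fit
#' @slot residualSigma residual standard deviation (area-ratio units)
#' @slot lod,loq detection / quantification limits (% w/w)
#' @slot nPoints calibration points used
#' @seealso [fitCalibrationCurve()], [quantifyEthanol()], [lodLoq()]
#' @export
setClass("CalibrationCurve",
  representation(
    slope         = "numeric",
    intercept     = "numeric",
    r2            = "numeric",
    residualSigma = "numeric",
    lod           = "numeric",
    loq           = "numeric",
    nPoints       = "integer"
  )
)

setValidity("CalibrationCurve", function(object) {
  if (object@slope == 0) return("calibration curve slope must be non-zero")
  if (object@residualSigma < 0) return("residual sigma must be >= 0")
  ok <- all.equal(object@lod * 10 / 3, object@loq, tolerance = 1e-12)
  if (!isTRUE(ok)) return("loq must equal (10/3) * lod")
  TRUE
})

## ---- accessors ----

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectrumSet", function(object) object@wavenumbers)

#' @rdname absorbance
#' @export
setMethod("absorbance", "SpectrumSet", function(object) object@absorbance)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SpectrumSet", function(object) object@sampleIds)

#' @rdname replicateOf
#' @export
setMethod("replicateOf", "SpectrumSet", function(object)
  if (length(object@replicateOf)) object@replicateOf else NULL)

#' Number of spectra in a set
#' @param x a [SpectrumSet-class]
#' @return integer sample count
#' @export
setMethod("length", "SpectrumSet", function(x) nrow(x@absorbance))

## ---- show methods ----

setMethod("show", "SpectrumSet", function(object) {
  g <- object@wavenumbers
  cat(sprintf("SpectrumSet: %d spectra x %d points, %g-%g cm-1 (step %g)\n",
              nrow(object@absorbance), length(g), min(g), max(g),
              if (length(g) > 1) g[2] - g[1] else NA_real_))
  if (length(object@replicateOf))
    cat(sprintf("  replicates of %d parent samples\n",
                length(unique(object@replicateOf))))
})

setMethod("show", "PretreatmentPipeline", function(object) {
  cat(sprintf("PretreatmentPipeline '%s' (%s)\n", object@name,
              if (object@fitted) "fitted" else "unfitted"))
  if (!length(object@steps)) {
    cat("  <identity>\n")
  } else {
    for (s in object@steps) {
      extra <- s[setdiff(names(s), "op")]
      cat(sprintf("  %s%s\n", s$op,
                  if (length(extra))
                    paste0("(", paste(names(extra), unlist(extra),
                                      sep = "=", collapse = ", "), ")")
                  else ""))
    }
  }
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variable(s), %d variables, pipeline '%s'\n",
              object@nLV, length(object@coefficients),
              object@pipeline@name))
})

setMethod("show", "ModelMetrics", function(object) {
  cat(sprintf("ModelMetrics (nLV = %d)\n", object@nLV))
  f <- function(lbl, v) if (!is.na(v)) cat(sprintf("  %-7s %.4g\n", lbl, v))
  f("RMSEE", object@rmsee);  f("SEC", object@sec);  f("R2cal", object@r2Cal)
  f("RMSECV", object@rmsecv); f("SECV", object@secv); f("R2cv", object@r2Cval)
  f("RMSEP", object@rmsep);  f("SEP", object@sep);  f("R2pred", object@r2Pred)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: ratio = %.5f x + %.5f (n = %d, r2 = %.4f)\n",
    object@slope, object@intercept, object@nPoints, object@r2))
  cat(sprintf("  residual sigma %.4g; LOD %.4g, LOQ %.4g %% w/w\n",
              object@residualSigma, object@lod, object@loq))
})

#' Coerce ModelMetrics to a one-row data frame
#'
#' @param x a [ModelMetrics-class]
#' @param row.names,optional,... ignored
#' @return one-row `data.frame` with the metric columns
#' @export
as.data.frame.ModelMetrics <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(nLV = x@nLV, rmsee = x@rmsee, sec = x@sec, r2Cal = x@r2Cal,
             rmsecv = x@rmsecv, secv = x@secv, r2Cval = x@r2Cval,
             rmsep = x@rmsep, sep = x@sep, r2Pred = x@r2Pred)
}

setAs("ModelMetrics", "data.frame",
      function(from) as.data.frame.ModelMetrics(from))

## internal: replace the absorbance matrix, keeping metadata
.withAbsorbance <- function(set, a) {
  rownames(a) <- set@sampleIds
  initialize(set, absorbance = a)
}
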