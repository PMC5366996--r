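#' Wavenumber grid of a spectrum set
#'
#' @param object a [SpectrumSet-class]
#' @return numeric vector of wavenumbers (cm-1), strictly increasing
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' Absorbance matrix of a spectrum set
#'
#' @param object a [SpectrumSet-class]
#' @return numeric matrix, samples in rows, grid points in columns
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' Sample identifiers
#'
#' @param object a [SpectrumSet-class]
#' @return character vector of unique sample labels
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' Replicate-to-parent mapping
#'
#' @param object a [SpectrumSet-class]
#' @return character vector mapping each spectrum to its parent sample, or
#'   `NULL` when the set carries no replicate structure
#' @export
setGeneric("replicateOf", function(object) standardGeneric("replicateOf"))

#' Restrict a spectrum set to a wavenumber window
#'
#' @param object a [SpectrumSet-class]
#' @param low,high window bounds in cm-1, inclusive; `low < high`
#' @return a [SpectrumSet-class] on the sub-grid
#' @export
setGeneric("selectRegion", function(object, low, high)
  standardGeneric("selectRegion"))

#' Average replicate spectra
#'
#' Collapses replicate groups (per [replicateOf()]) to their pointwise
#' arithmetic mean, one spectrum per parent sample. Singleton groups pass
#' through unchanged.
#'
#' @param object a [SpectrumSet-class] with a replicate mapping
#' @return a [SpectrumSet-class] with one spectrum per parent sample
#' @export
setGeneric("averageReplicates", function(object)
  standardGeneric("averageReplicates"))

#' Subtract each spectrum's minimum
#'
#' @param object a [SpectrumSet-class]
#' @return a [SpectrumSet-class]; every spectrum has minimum exactly 0
#' @export
setGeneric("subtractMinimum", function(object)
  standardGeneric("subtractMinimum"))

#' Per-spectrum normalization
#'
#' @param object a [SpectrumSet-class]
#' @param method `"minmax"` (default; values scaled to `[0, 1]`),
#'   `"vector"` (unit Euclidean norm) or `"area"` (unit integral over the
#'   grid)
#' @return a [SpectrumSet-class]
#' @export
setGeneric("normalizeSpectra", function(object, method = "minmax")
  standardGeneric("normalizeSpectra"))

#' Savitzky-Golay derivative with respect to wavenumber
#'
#' @param object a [SpectrumSet-class] on a uniform grid
#' @param order derivative order, 1 or 2
#' @param window odd filter window length (points); must exceed `polyorder`
#' @param polyorder fitting polynomial degree; defaults to 2 for first and 3
#'   for second derivatives
#' @return a [SpectrumSet-class] of derivative spectra (AU per cm-1 to the
#'   `order`); full grid length is kept, edges handled by the filter's
#'   end-window polynomial fits
#' @export
setGeneric("spectralDerivative",
  function(object, order, window = 9L, polyorder = NULL)
    standardGeneric("spectralDerivative"))

#' Column mean centering
#'
#' @param object a [SpectrumSet-class]
#' @param means per-wavenumber means to subtract; when `NULL` they are
#'   computed from `object` (requires at least 2 samples)
#' @return a [SpectrumSet-class]; with `means = NULL` every column mean of
#'   the result is 0
#' @export
setGeneric("meanCenter", function(object, means = NULL)
  standardGeneric("meanCenter"))

#' Learn the data-dependent state of a pre-treatment pipeline
#'
#' @param pipeline a [PretreatmentPipeline-class]
#' @param object the calibration [SpectrumSet-class]
#' @return the pipeline with `fitted = TRUE` and per-step state (e.g. column
#'   means for mean centering) stored
#' @export
setGeneric("fitPipeline", function(pipeline, object)
  standardGeneric("fitPipeline"))

#' Apply a pre-treatment pipeline
#'
#' Uses the state learned by [fitPipeline()]; never re-estimates it from the
#' new data.
#'
#' @param pipeline a fitted [PretreatmentPipeline-class] (pipelines without
#'   data-dependent steps may be applied unfitted)
#' @param object a [SpectrumSet-class]
#' @return the transformed [SpectrumSet-class]
#' @export
setGeneric("applyPipeline", function(pipeline, object)
  standardGeneric("applyPipeline"))

#' Detection and quantification limits of a calibration curve
#'
#' @param object a [CalibrationCurve-class]
#' @return named numeric vector `c(lod = 3 * sigma / |slope|,
#'   loq = 10 * sigma / |slope|)` where sigma is the residual standard
#'   deviation of the regression
#' @export
setGeneric("lodLoq", function(object) standardGeneric("lodLoq"))
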