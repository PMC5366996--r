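#' @include AllClasses.R
NULL

## coefficients of the reference % w/w -> % v/v conversion line used with
## the GC method (v/v = 1.21879 * w/w + 0.13712)
.WW_TO_VV <- c(slope = 1.21879, intercept = 0.13712)

#' Fit an internal-standard GC-FID calibration curve
#'
#' Ordinary least-squares line of ethanol:n-propanol peak-area ratio
#' against ethanol concentration (% w/w). The residual standard deviation
#' (n - 2 degrees of freedom) feeds the 3-sigma / 10-sigma detection and
#' quantification limits.
#'
#' @param concentration ethanol concentrations of the standards (% w/w), at
#'   least 3 distinct values
#' @param areaRatio ethanol:n-propanol peak-area ratios; alternatively pass
#'   `areaEthanol` and `areaPropanol` and the ratio is formed internally
#' @param areaEthanol,areaPropanol raw peak areas (used when `areaRatio` is
#'   missing)
#' @return a [CalibrationCurve-class]
#' @examples
#' x <- c(1, 5, 10, 25, 50)
#' fitCalibrationCurve(x, 0.13903 * x + 0.04488)
#' @export
fitCalibrationCurve <- function(concentration, areaRatio = NULL,
                                areaEthanol = NULL, areaPropanol = NULL) {
  if (is.null(areaRatio)) {
    if (is.null(areaEthanol) || is.null(areaPropanol))
      stop("fitCalibrationCurve: give areaRatio, or areaEthanol and areaPropanol")
    if (any(areaPropanol == 0))
      stop("fitCalibrationCurve: zero internal-standard peak area")
    areaRatio <- areaEthanol / areaPropanol
  }
  n <- length(concentration)
  if (n != length(areaRatio))
    stop("fitCalibrationCurve: concentration and area ratio lengths differ")
  if (length(unique(concentration)) < 3L)
    stop("fitCalibrationCurve: need at least 3 distinct concentrations")
  fit <- stats::lm(areaRatio ~ concentration)
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / (n - 2))
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("fitCalibrationCurve: zero slope")
  sst <- sum((areaRatio - mean(areaRatio))^2)
  new("CalibrationCurve",
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r2 = 1 - sum(res^2) / sst,
      residualSigma = sigma,
      lod = 3 * sigma / abs(slope),
      loq = 10 * sigma / abs(slope),
      nPoints = as.integer(n))
}

#' Quantify ethanol from a peak-area ratio
#'
#' Inverts the calibration line: `x = (y - intercept) / slope`. Negative
#' results (ratios below the intercept) are returned as-is with a warning,
#' never clipped: they signal a sample below the calibration range.
#'
#' @param curve a [CalibrationCurve-class]
#' @param areaRatio ethanol:n-propanol peak-area ratio(s)
#' @return ethanol concentration(s), % w/w
#' @export
quantifyEthanol <- function(curve, areaRatio) {
  x <- (areaRatio - curve@intercept) / curve@slope
  if (any(x < 0))
    warning(sprintf(
      "quantifyEthanol: %d result(s) below zero (below calibration range)",
      sum(x < 0)))
  x
}

#' @rdname lodLoq
#' @export
setMethod("lodLoq", "CalibrationCurve", function(object)
  c(lod = object@lod, loq = object@loq))

#' Convert ethanol % w/w to % v/v
#'
#' By default uses the empirical affine conversion established alongside
#' the GC reference method (`v/v = 1.21879 w/w + 0.13712`), reproduced as
#' printed even though its intercept is non-physical at 0 % w/w. Set
#' `method = "density"` for a physically-motivated alternative that scales
#' by the water/ethanol density ratio at 20 C and passes through the
#' origin (approximation valid for dilute beverages).
#'
#' @param x ethanol concentration, % w/w (non-negative)
#' @param method `"affine"` (default, the reference line) or `"density"`
#' @return ethanol concentration, % v/v
#' @examples
#' wwToVv(3.27)            # 4.12 (3 s.f.)
#' wwToVv(3.27, "density")
#' @export
wwToVv <- function(x, method = c("affine", "density")) {
  method <- match.arg(method)
  if (any(x < 0)) stop("wwToVv: concentrations must be >= 0")
  if (method == "affine")
    .WW_TO_VV["slope"] * x + .WW_TO_VV["intercept"]
  else
    x * 0.99821 / 0.78924   # rho_water / rho_ethanol at 20 C
}

#' Inverse of [wwToVv()]
#'
#' @param y ethanol concentration, % v/v
#' @param method see [wwToVv()]
#' @return ethanol concentration, % w/w
#' @export
vvToWw <- function(y, method = c("affine", "density")) {
  method <- match.arg(method)
  if (method == "affine")
    (y - .WW_TO_VV["intercept"]) / .WW_TO_VV["slope"]
  else
    y * 0.78924 / 0.99821
}

#' Read a GC-FID calibration table from CSV
#'
#' Expects either columns `concentration_ww_percent` and `area_ratio`, or
#' `concentration_ww_percent`, `area_ethanol` and `area_propanol` (the
#' ratio is then formed internally).
#'
#' @param path CSV file
#' @return a [CalibrationCurve-class]
#' @export
readGCTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cc <- df[["concentration_ww_percent"]]
  if (is.null(cc))
    stop("readGCTable: column 'concentration_ww_percent' required")
  if (!is.null(df[["area_ratio"]]))
    fitCalibrationCurve(cc, areaRatio = df[["area_ratio"]])
  else
    fitCalibrationCurve(cc, areaEthanol = df[["area_ethanol"]],
                        areaPropanol = df[["area_propanol"]])
}

#' Serialize a calibration curve to JSON
#'
#' @param curve a [CalibrationCurve-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCalibrationCurve <- function(curve, path) {
  jsonlite::write_json(
    list(format = "mirpls-gc-curve", version = 1L,
         slope = curve@slope, intercept = curve@intercept, r2 = curve@r2,
         residualSigma = curve@residualSigma, lod = curve@lod,
         loq = curve@loq, nPoints = curve@nPoints),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
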