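#' @include spectra-io.R
NULL

#' @rdname subtractMinimum
#' @export
setMethod("subtractMinimum", "SpectrumSet", function(object) {
  a <- object@absorbance
  if (!nrow(a)) stop("subtractMinimum: empty spectrum set")
  .withAbsorbance(object, a - apply(a, 1, min))
})

#' @rdname normalizeSpectra
#' @export
setMethod("normalizeSpectra", "SpectrumSet",
          function(object, method = "minmax") {
  method <- match.arg(method, c("minmax", "vector", "area"))
  a <- object@absorbance
  out <- switch(method,
    minmax = {
      rng <- apply(a, 1, function(r) diff(range(r)))
      if (any(rng == 0))
        stop(sprintf(
          "normalizeSpectra: flat (zero-range) spectrum: %s",
          paste(object@sampleIds[rng == 0], collapse = ", ")))
      (a - apply(a, 1, min)) / rng
    },
    vector = {
      nrm <- sqrt(rowSums(a^2))
      if (any(nrm == 0))
        stop("normalizeSpectra: zero spectrum cannot be vector-normalized")
      a / nrm
    },
    area = {
      dx <- object@wavenumbers[2] - object@wavenumbers[1]
      ar <- rowSums(a) * dx
      if (any(ar == 0))
        stop("normalizeSpectra: zero-area spectrum")
      a / ar
    })
  .withAbsorbance(object, out)
})

#' @rdname spectralDerivative
#' @export
setMethod("spectralDerivative", "SpectrumSet",
          function(object, order, window = 9L, polyorder = NULL) {
  if (!order %in% c(1L, 2L))
    stop("spectralDerivative: order must be 1 or 2")
  if (is.null(polyorder)) polyorder <- if (order == 1L) 2L else 3L
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("spectralDerivative: window must be odd")
  if (window <= polyorder || polyorder < order)
    stop("spectralDerivative: need window > polyorder >= order")
  g <- object@wavenumbers
  if (window >= length(g))
    stop(sprintf("spectralDerivative: window (%d) must be shorter than the grid (%d)",
                 window, length(g)))
  dx <- g[2] - g[1]
  a <- t(apply(object@absorbance, 1, signal::sgolayfilt,
               p = polyorder, n = window, m = order, ts = dx))
  .withAbsorbance(object, a)
})

#' @rdname meanCenter
#' @export
setMethod("meanCenter", "SpectrumSet", function(object, means = NULL) {
  a <- object@absorbance
  if (is.null(means)) {
    if (nrow(a) < 2L)
      stop("meanCenter: fitting column means requires at least 2 samples; ",
           "pass stored means to centre new spectra")
    means <- colMeans(a)
  }
  if (length(means) != ncol(a))
    stop("meanCenter: means length does not match the grid")
  .withAbsorbance(object, sweep(a, 2, means))
})

## registry of the named pre-treatment chains, in the order the operators
## are applied (left to right)
.PIPELINES <- list(
  "raw" = character(0),
  "sub_min+1st_derivative" =
    c("subtract_minimum", "derivative1"),
  "sub_min+2nd_derivative" =
    c("subtract_minimum", "derivative2"),
  "sub_min+1st_derivative+mean_centering" =
    c("subtract_minimum", "derivative1", "mean_center"),
  "sub_min+2nd_derivative+mean_centering" =
    c("subtract_minimum", "derivative2", "mean_center"),
  "sub_min+mean_centering" =
    c("subtract_minimum", "mean_center"),
  "sub_min+normalization" =
    c("subtract_minimum", "normalize"),
  "sub_min+normalization+mean_centering" =
    c("subtract_minimum", "normalize", "mean_center"),
  "sub_min+normalization+1st_derivative" =
    c("subtract_minimum", "normalize", "derivative1"),
  "sub_min+normalization+2nd_derivative" =
    c("subtract_minimum", "normalize", "derivative2"),
  "sub_min+normalization+1st_derivative+mean_centering" =
    c("subtract_minimum", "normalize", "derivative1", "mean_center"),
  "sub_min+normalization+2nd_derivative+mean_centering" =
    c("subtract_minimum", "normalize", "derivative2", "mean_center")
)

#' Names of the registered pre-treatment chains
#'
#' Eleven named chains combining minimum subtraction, min-max
#' normalization, first/second Savitzky-Golay derivatives and mean
#' centering, plus `"raw"` (the identity).
#'
#' @return character vector of valid [buildPipeline()] names
#' @export
pipelineNames <- function() names(.PIPELINES)

#' Build a named pre-treatment pipeline
#'
#' @param name one of [pipelineNames()]
#' @param window,polyorder1,polyorder2 Savitzky-Golay settings used by any
#'   derivative step (window length in points; polynomial degrees for first
#'   and second derivatives)
#' @param normMethod normalization variant, see [normalizeSpectra()]
#' @return an unfitted [PretreatmentPipeline-class]
#' @examples
#' buildPipeline("sub_min+2nd_derivative")
#' @export
buildPipeline <- function(name, window = 9L, polyorder1 = 2L,
                          polyorder2 = 3L, normMethod = "minmax") {
  if (!name %in% names(.PIPELINES))
    stop(sprintf("unknown pipeline '%s'; valid names: %s",
                 name, paste(names(.PIPELINES), collapse = ", ")))
  steps <- lapply(.PIPELINES[[name]], function(tag)
    switch(tag,
      subtract_minimum = list(op = "subtract_minimum"),
      normalize = list(op = "normalize", method = normMethod),
      derivative1 = list(op = "derivative", order = 1L,
                         window = as.integer(window),
                         polyorder = as.integer(polyorder1)),
      derivative2 = list(op = "derivative", order = 2L,
                         window = as.integer(window),
                         polyorder = as.integer(polyorder2)),
      mean_center = list(op = "mean_center")))
  new("PretreatmentPipeline", name = name, steps = steps,
      fitted = FALSE, state = vector("list", length(steps)))
}

#' Read a pipeline declaration from a YAML or JSON config file
#'
#' The config holds either `pipeline: <registry name>` or an explicit
#' `steps:` list of `op:` entries with their parameters.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`)
#' @return an unfitted [PretreatmentPipeline-class]
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$pipeline))
    return(do.call(buildPipeline,
                   c(list(name = cfg$pipeline),
                     cfg[intersect(names(cfg),
                         c("window", "polyorder1", "polyorder2",
                           "normMethod"))])))
  if (is.null(cfg$steps)) stop("config needs 'pipeline' or 'steps'")
  steps <- lapply(cfg$steps, function(s) {
    s$op <- as.character(s$op)
    for (f in c("order", "window", "polyorder"))
      if (!is.null(s[[f]])) s[[f]] <- as.integer(s[[f]])
    s
  })
  new("PretreatmentPipeline", name = cfg$name %||% "custom", steps = steps,
      fitted = FALSE, state = vector("list", length(steps)))
}

## sequential walk shared by fit and apply
.pipelineWalk <- function(pipeline, object, fit) {
  state <- pipeline@state
  for (i in seq_along(pipeline@steps)) {
    s <- pipeline@steps[[i]]
    object <- switch(s$op,
      subtract_minimum = subtractMinimum(object),
      normalize = normalizeSpectra(object, s$method %||% "minmax"),
      derivative = spectralDerivative(object, s$order,
                                      window = s$window %||% 9L,
                                      polyorder = s$polyorder),
      mean_center = {
        if (fit) {
          state[[i]] <- list(columnMeans = colMeans(object@absorbance))
          meanCenter(object, state[[i]]$columnMeans)
        } else {
          if (is.null(state[[i]]$columnMeans))
            stop("applyPipeline: pipeline with mean centering has not been ",
                 "fitted; call fitPipeline() on the calibration set first")
          meanCenter(object, state[[i]]$columnMeans)
        }
      },
      stop("unsupported pipeline step: ", s$op))
  }
  list(object = object, state = state)
}

#' @rdname fitPipeline
#' @export
setMethod("fitPipeline", c("PretreatmentPipeline", "SpectrumSet"),
          function(pipeline, object) {
  if (length(pipeline@state) != length(pipeline@steps))
    pipeline@state <- vector("list", length(pipeline@steps))
  res <- .pipelineWalk(pipeline, object, fit = TRUE)
  initialize(pipeline, fitted = TRUE, state = res$state)
})

#' @rdname applyPipeline
#' @export
setMethod("applyPipeline", c("PretreatmentPipeline", "SpectrumSet"),
          function(pipeline, object) {
  needsState <- any(vapply(pipeline@steps,
                           function(s) s$op == "mean_center", TRUE))
  if (needsState && !pipeline@fitted)
    stop("applyPipeline: pipeline with mean centering has not been fitted; ",
         "call fitPipeline() on the calibration set first")
  if (length(pipeline@state) != length(pipeline@steps))
    pipeline@state <- vector("list", length(pipeline@steps))
  .pipelineWalk(pipeline, object, fit = FALSE)$object
})
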