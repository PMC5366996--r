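#' @include preprocess.R
NULL

## subset a SpectrumSet by sample index or id; exported via rawNamespace
## (see mirpls-package.R)
setMethod("[", signature(x = "SpectrumSet", i = "ANY", j = "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  initialize(x,
    absorbance = x@absorbance[i, , drop = FALSE],
    sampleIds = x@sampleIds[i],
    replicateOf = if (length(x@replicateOf)) x@replicateOf[i]
                  else character(0))
})

## coerce matrix input to a SpectrumSet on an index grid so that the
## pipeline operators (which need a grid) apply uniformly
.asSet <- function(x) {
  if (is(x, "SpectrumSet")) return(x)
  SpectrumSet(as.matrix(x), seq_len(ncol(as.matrix(x))))
}

## ---- NIPALS PLS1 core ----

## Fits maxLV components once; the NIPALS sequence is nested, so the
## regression vector for any a <= maxLV is recoverable from the first a
## weights/loadings. X deflated per component; y centred only.
.nipals <- function(X, y, maxLV, tol = 1e-12, allowPartial = FALSE) {
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("fitPLS: X rows and y length differ")
  if (anyNA(X) || anyNA(y)) stop("fitPLS: missing values not allowed")
  if (maxLV < 1L) stop("fitPLS: need at least 1 latent variable")
  if (maxLV > min(n - 1L, p))
    stop(sprintf("fitPLS: %d latent variables exceed min(samples - 1, variables) = %d",
                 maxLV, min(n - 1L, p)))
  if (stats::var(y) == 0)
    stop("fitPLS: response has zero variance")
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  sx <- sqrt(mean(E^2))              # scale for rank tolerance
  if (sx == 0) stop("fitPLS: spectra have zero variance")
  W <- P <- matrix(0, p, maxLV)
  Tm <- matrix(0, n, maxLV)
  q <- numeric(maxLV)
  nComp <- 0L
  for (h in seq_len(maxLV)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    exhausted <- nw <= tol * sx * n
    if (!exhausted) {
      w <- w / nw
      t <- drop(E %*% w)
      tt <- sum(t^2)
      exhausted <- tt <= (tol * sx)^2 * n
    }
    if (exhausted) {
      if (allowPartial && h > 1L) break
      stop(sprintf("fitPLS: data rank exhausted at component %d of %d",
                   h, maxLV))
    }
    pvec <- drop(crossprod(E, t)) / tt
    q[h] <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    W[, h] <- w; P[, h] <- pvec; Tm[, h] <- t
    nComp <- h
  }
  list(W = W[, seq_len(nComp), drop = FALSE],
       P = P[, seq_len(nComp), drop = FALSE],
       q = q[seq_len(nComp)],
       scores = Tm[, seq_len(nComp), drop = FALSE],
       xMean = xm, yMean = ym, nComp = nComp)
}

## regression vector and intercept for the first a extracted components
## (capped at what the data's rank allowed)
.nipalsCoef <- function(fit, a) {
  a <- min(a, fit$nComp)
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  B <- drop(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
  list(coefficients = B, intercept = fit$yMean - sum(fit$xMean * B))
}

#' Fit a PLS1 calibration model (NIPALS)
#'
#' Centres the spectra and the response, then extracts `nLV` latent
#' variables by the NIPALS algorithm (X-block deflation; the single
#' response is centred only). The result is deterministic and is collapsed
#' into a single regression vector, so prediction is one affine map of a
#' pre-treated spectrum. When `pipeline` is given it is fitted on `x`
#' first and stored in the model; [predict()] then re-applies it (with its
#' stored state) to new spectra.
#'
#' @param x calibration spectra: a [SpectrumSet-class] or a numeric matrix
#'   (samples x variables)
#' @param y response, e.g. ethanol concentration (% w/w)
#' @param nLV number of latent variables, `1 <= nLV <= min(n - 1, p)`
#' @param pipeline optional [PretreatmentPipeline-class] applied before the
#'   regression (fitted here on `x`)
#' @return a [PLSModel-class]
#' @examples
#' sim <- simulateDataset(SimConfig(seed = 1))
#' cal <- averageReplicates(sim$spectra)
#' m <- fitPLS(cal, sim$design$ethanol, nLV = 6,
#'             pipeline = buildPipeline("sub_min+2nd_derivative"))
#' @export
fitPLS <- function(x, y, nLV, pipeline = NULL) {
  set <- .asSet(x)
  if (is.null(pipeline)) pipeline <- buildPipeline("raw")
  pipeline <- fitPipeline(pipeline, set)
  pre <- applyPipeline(pipeline, set)
  fit <- .nipals(pre@absorbance, y, as.integer(nLV))
  cf <- .nipalsCoef(fit, as.integer(nLV))
  fitted <- drop(pre@absorbance %*% cf$coefficients) + cf$intercept
  new("PLSModel",
      nLV = as.integer(nLV),
      weights = fit$W, xLoadings = fit$P, yLoadings = fit$q,
      scores = fit$scores, xMean = fit$xMean, yMean = fit$yMean,
      coefficients = cf$coefficients, intercept = cf$intercept,
      fittedValues = stats::setNames(fitted, set@sampleIds),
      grid = if (is(x, "SpectrumSet")) x@wavenumbers else numeric(0),
      pipeline = pipeline)
}

#' Predict ethanol concentrations from spectra
#'
#' Applies the model's stored pre-treatment pipeline (using the state
#' learned at fit time, never re-estimated) and then the collapsed
#' regression map. The new spectra must live on the training grid.
#'
#' @param object a [PLSModel-class]
#' @param newdata a [SpectrumSet-class] (or matrix with one column per
#'   training variable)
#' @param ... ignored
#' @return named numeric vector of predictions (% w/w)
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  set <- .asSet(newdata)
  if (length(object@grid)) {
    if (is(newdata, "SpectrumSet")) {
      if (length(set@wavenumbers) != length(object@grid) ||
          max(abs(set@wavenumbers - object@grid)) >
            .GRID_RTOL * max(abs(object@grid)))
        stop("predict: spectra are not on the model's training grid")
    } else if (ncol(set@absorbance) != length(object@grid)) {
      stop("predict: spectra are not on the model's training grid")
    } else {
      set <- SpectrumSet(set@absorbance, object@grid,
                         sampleIds = set@sampleIds)
    }
  }
  pre <- applyPipeline(object@pipeline, set)
  stats::setNames(
    drop(pre@absorbance %*% object@coefficients) + object@intercept,
    set@sampleIds)
})

## ---- PCA screening ----

#' PCA screening for clusters and outliers
#'
#' Column-centred principal component analysis (via SVD) of the spectra,
#' with per-sample Hotelling T-squared in the first `nComponents` score
#' dimensions. Samples above the (1 - alpha) T-squared limit
#' (`k (n-1)(n+1) / (n (n-k))` times the F quantile) are flagged; the
#' function warns about them but never drops them.
#'
#' @param x a [SpectrumSet-class] or numeric matrix (samples x variables)
#' @param nComponents score dimensions used for the T-squared statistic
#'   (must be < number of samples)
#' @param alpha flagging level (default 0.05)
#' @return `data.frame` with sample ids, scores, `t2` and `outlier` flag;
#'   attributes `explainedVariance` (fraction per component, over all
#'   components of the data) and `t2Limit`
#' @export
pcaScreen <- function(x, nComponents = 2L, alpha = 0.05) {
  X <- .asSet(x)@absorbance
  ids <- .asSet(x)@sampleIds
  n <- nrow(X)
  if (n < 3L) stop("pcaScreen: need at least 3 samples")
  k <- as.integer(nComponents)
  if (k >= n)
    stop(sprintf("pcaScreen: nComponents (%d) must be below the sample count (%d)",
                 k, n))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = k, nv = 0)
  vars <- sv$d^2 / (n - 1)
  total <- sum(vars)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  compVar <- vars[seq_len(k)]
  pos <- compVar > 1e-12 * max(total, .Machine$double.eps)
  t2 <- rowSums(sweep(scores[, pos, drop = FALSE], 2,
                      sqrt(compVar[pos]), "/")^2)
  lim <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    stats::qf(1 - alpha, k, n - k)
  out <- t2 > lim
  if (any(out))
    warning(sprintf("pcaScreen: %d sample(s) above the T2 limit: %s",
                    sum(out), paste(ids[out], collapse = ", ")))
  res <- data.frame(sampleId = ids, scores, t2 = t2, outlier = out)
  names(res)[1 + seq_len(k)] <- paste0("PC", seq_len(k))
  attr(res, "explainedVariance") <-
    if (total > 0) vars / total else vars
  attr(res, "t2Limit") <- lim
  res
}

## ---- cross-validation and model selection ----

## out-of-fold predictions for every component count 1..maxLV; the
## pipeline (including its mean-centring state) is re-fitted inside each
## fold so no information leaks from the held-out sample
.looPredictions <- function(set, y, pipeline, maxLV, allowPartial = FALSE) {
  n <- length(set)
  preds <- matrix(NA_real_, n, maxLV)
  for (i in seq_len(n)) {
    fold <- tryCatch({
      pl <- fitPipeline(pipeline, set[-i])
      pre <- applyPipeline(pl, set[-i])
      fit <- .nipals(pre@absorbance, y[-i], maxLV,
                     allowPartial = allowPartial)
      hold <- applyPipeline(pl, set[i])@absorbance
      vapply(seq_len(maxLV), function(a) {
        cf <- .nipalsCoef(fit, a)
        drop(hold %*% cf$coefficients) + cf$intercept
      }, 0)
    }, error = function(e)
      stop(sprintf("loo_cv: fold %d (held-out '%s') failed: %s",
                   i, set@sampleIds[i], conditionMessage(e)),
           call. = FALSE))
    preds[i, ] <- fold
  }
  rownames(preds) <- set@sampleIds
  preds
}

#' Leave-one-out cross-validation of a PLS1 calibration
#'
#' For each of the n samples, the pre-treatment pipeline and the PLS model
#' are re-fitted on the remaining n - 1 spectra and the held-out sample is
#' predicted, giving n out-of-fold predictions (n sub-models in total).
#' Calibration-set figures (RMSEE, SEC, R2) come from the model fitted on
#' all n samples.
#'
#' @param x calibration spectra ([SpectrumSet-class] or matrix), raw
#'   (un-pre-treated)
#' @param y response (% w/w)
#' @param pipeline a [PretreatmentPipeline-class] (default `"raw"`)
#' @param nLV latent variables
#' @return a [ModelMetrics-class] carrying rmsee/sec/r2Cal,
#'   rmsecv/secv/r2Cval and the per-sample out-of-fold predictions
#' @export
looCV <- function(x, y, pipeline = NULL, nLV = 6L) {
  set <- .asSet(x)
  if (length(set) < 3L) stop("loo_cv: need at least 3 samples")
  if (is.null(pipeline)) pipeline <- buildPipeline("raw")
  nLV <- as.integer(nLV)
  cvp <- .looPredictions(set, y, pipeline, nLV)[, nLV]
  full <- fitPLS(set, y, nLV, pipeline)
  new("ModelMetrics",
      nLV = nLV,
      rmsee = rmse(full@fittedValues, y),
      sec = standardError(full@fittedValues, y, nLV),
      r2Cal = rSquared(full@fittedValues, y),
      rmsecv = rmse(cvp, y),
      secv = standardError(cvp, y, nLV),
      r2Cval = rSquared(cvp, y),
      cvPredictions = cvp)
}

#' Choose the number of latent variables by parsimony
#'
#' Computes the leave-one-out RMSECV for 1..`maxLV` components and returns
#' the smallest count whose RMSECV is within a margin of the curve
#' minimum, rather than the argmin: past the elbow extra components fit
#' noise without improving prediction. The margin is the larger of a
#' relative tolerance (`tol`, default 2 %) and one standard error of the
#' minimum RMSECV (delta method over the held-out squared errors) - with
#' a handful of CV folds, differences inside one standard error do not
#' justify extra components.
#'
#' @inheritParams looCV
#' @param maxLV largest component count tried (capped at n - 2)
#' @param tol relative tolerance on the RMSECV minimum (default 0.02)
#' @return list with `nLV` (chosen), `rmsecvCurve` (per-LV RMSECV) and
#'   `margin` (the absolute tolerance applied to the minimum)
#' @export
selectNLV <- function(x, y, pipeline = NULL, maxLV = 10L, tol = 0.02) {
  set <- .asSet(x)
  if (is.null(pipeline)) pipeline <- buildPipeline("raw")
  maxLV <- min(as.integer(maxLV), length(set) - 2L,
               ncol(set@absorbance))
  if (maxLV < 1L) stop("select_n_lv: too few samples")
  # folds whose rank runs out early reuse their largest extractable model
  # for the higher counts, so the curve flattens instead of erroring
  preds <- .looPredictions(set, y, pipeline, maxLV, allowPartial = TRUE)
  curve <- apply(preds, 2, rmse, reference = y)
  names(curve) <- seq_len(maxLV)
  aMin <- which.min(curve)
  best <- curve[aMin]
  # one standard error of the minimum RMSECV: SE of the mean squared
  # held-out error, propagated through the square root
  sq <- (preds[, aMin] - y)^2
  seBest <- if (best > 0)
    stats::sd(sq) / sqrt(length(sq)) / (2 * best) else 0
  margin <- max(tol * best, seBest)
  nLV <- which(curve <= best + margin)[1]
  list(nLV = as.integer(nLV), rmsecvCurve = curve,
       margin = unname(margin))
}

#' Compare pre-treatment chains on a calibration/validation split
#'
#' For each named chain: the component count is chosen by [selectNLV()] on
#' the calibration set, the model is refitted at that count, and
#' calibration (RMSEE, R2) and external-validation (RMSEP, R2) figures are
#' computed. Rows are ranked lexicographically: higher validation R2, then
#' lower RMSEP, then fewer latent variables, then input order. A chain
#' that fails (e.g. a degenerate transform) yields a row of `NA`s flagged
#' `failed`, not an error.
#'
#' @param xCal,yCal calibration spectra and response
#' @param xVal,yVal external validation spectra and response
#' @param pipelines character vector of [pipelineNames()]
#' @param maxLV largest component count tried per chain
#' @param tol parsimony tolerance passed to [selectNLV()]
#' @return `data.frame`, one row per chain, ranked best first; columns
#'   `pipeline`, `nLV`, `rmsee`, `r2Cal`, `rmsecv`, `r2Cval`, `rmsep`,
#'   `r2Pred`, `failed`
#' @export
comparePretreatments <- function(xCal, yCal, xVal, yVal,
                                 pipelines, maxLV = 10L, tol = 0.02) {
  bad <- setdiff(pipelines, pipelineNames())
  if (length(bad))
    stop("unknown pipeline(s): ", paste(bad, collapse = ", "))
  rows <- lapply(pipelines, function(nm) {
    tryCatch({
      pl <- buildPipeline(nm)
      sel <- selectNLV(xCal, yCal, pl, maxLV = maxLV, tol = tol)
      cv <- looCV(xCal, yCal, pl, sel$nLV)
      model <- fitPLS(xCal, yCal, sel$nLV, pl)
      pv <- predict(model, xVal)
      data.frame(pipeline = nm, nLV = sel$nLV,
                 rmsee = cv@rmsee, r2Cal = cv@r2Cal,
                 rmsecv = cv@rmsecv, r2Cval = cv@r2Cval,
                 rmsep = rmse(pv, yVal), r2Pred = rSquared(pv, yVal),
                 failed = FALSE)
    }, error = function(e)
      data.frame(pipeline = nm, nLV = NA_integer_,
                 rmsee = NA_real_, r2Cal = NA_real_,
                 rmsecv = NA_real_, r2Cval = NA_real_,
                 rmsep = NA_real_, r2Pred = NA_real_, failed = TRUE))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$failed, -tab$r2Pred, tab$rmsep, tab$nLV,
               seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## ---- model serialization ----

#' Write a fitted PLS model to JSON
#'
#' Serializes everything [predict()] needs (grid, pipeline with fitted
#' state, regression vector) plus the latent-variable decomposition.
#'
#' @param model a [PLSModel-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writePLSModel <- function(model, path) {
  pl <- model@pipeline
  obj <- list(
    format = "mirpls-pls-model", version = 1L,
    nLV = model@nLV,
    grid = model@grid,
    pipeline = list(name = pl@name, steps = pl@steps,
                    fitted = pl@fitted, state = pl@state),
    xMean = model@xMean, yMean = model@yMean,
    weights = model@weights, xLoadings = model@xLoadings,
    yLoadings = model@yLoadings, scores = model@scores,
    coefficients = model@coefficients, intercept = model@intercept,
    fittedValues = as.list(model@fittedValues))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PLS model written by [writePLSModel()]
#'
#' @param path JSON file
#' @return a [PLSModel-class]
#' @export
readPLSModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "mirpls-pls-model"))
    stop("not a mirpls PLS model file: ", path)
  steps <- lapply(obj$pipeline$steps, function(s) {
    for (f in c("order", "window", "polyorder"))
      if (!is.null(s[[f]])) s[[f]] <- as.integer(s[[f]])
    s
  })
  state <- lapply(obj$pipeline$state, function(s) {
    if (is.null(s) || !length(s)) NULL
    else list(columnMeans = as.numeric(s$columnMeans))
  })
  pl <- new("PretreatmentPipeline", name = obj$pipeline$name,
            steps = steps, fitted = isTRUE(obj$pipeline$fitted),
            state = state)
  new("PLSModel",
      nLV = as.integer(obj$nLV),
      weights = as.matrix(obj$weights),
      xLoadings = as.matrix(obj$xLoadings),
      yLoadings = as.numeric(obj$yLoadings),
      scores = as.matrix(obj$scores),
      xMean = as.numeric(obj$xMean), yMean = as.numeric(obj$yMean),
      coefficients = as.numeric(obj$coefficients),
      intercept = as.numeric(obj$intercept),
      fittedValues = unlist(obj$fittedValues),
      grid = as.numeric(obj$grid),
      pipeline = pl)
}
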