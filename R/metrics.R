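#' @include AllClasses.R
NULL

#' Root mean square error
#'
#' @param predicted,reference equal-length numeric vectors (% w/w)
#' @return `sqrt(mean((predicted - reference)^2))`
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted))
    stop("rmse: predicted and reference must have equal non-zero length")
  sqrt(mean((predicted - reference)^2))
}

#' Degrees-of-freedom-corrected standard error (SEC/SECV/SEP)
#'
#' The analogue of [rmse()] with denominator `n - nLV - 1`, the convention
#' for the standard error of calibration/cross-validation/prediction of a
#' latent-variable model.
#'
#' @inheritParams rmse
#' @param nLV latent variables consumed by the model (0 for an external
#'   prediction set)
#' @return `sqrt(sum((predicted - reference)^2) / (n - nLV - 1))`
#' @export
standardError <- function(predicted, reference, nLV) {
  n <- length(predicted)
  if (n != length(reference))
    stop("standardError: length mismatch")
  if (n <= nLV + 1)
    stop(sprintf("standardError: need n > nLV + 1 (n = %d, nLV = %d)",
                 n, nLV))
  sqrt(sum((predicted - reference)^2) / (n - nLV - 1))
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` of predictions against a reference; 1 for a perfect
#' prediction, 0 when the predictions do no better than the reference mean.
#'
#' @inheritParams rmse
#' @return dimensionless, at most 1
#' @export
rSquared <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted))
    stop("rSquared: predicted and reference must have equal non-zero length")
  sstot <- sum((reference - mean(reference))^2)
  if (sstot == 0)
    stop("rSquared: reference has zero variance")
  1 - sum((predicted - reference)^2) / sstot
}

#' Spike-recovery of one sample
#'
#' Percent recovery of a known spike:
#' `100 * (spiked - unspiked) / added`. Invariant under adding a constant
#' to both the unspiked and spiked determinations, so matrix offsets cancel.
#'
#' @param unspiked concentration found before spiking (% w/w)
#' @param spiked concentration found after spiking (% w/w)
#' @param added amount of analyte added (% w/w), must be positive
#' @return list with fields `unspiked`, `spiked`, `added` and
#'   `percentRecovery` (full precision; round only for presentation)
#' @examples
#' recovery(6.64, 9.03, 2.80)$percentRecovery  # 85.4 (3 s.f.)
#' @export
recovery <- function(unspiked, spiked, added) {
  if (!is.finite(added) || added <= 0)
    stop("recovery: amount added must be positive")
  list(unspiked = unspiked, spiked = spiked, added = added,
       percentRecovery = 100 * (spiked - unspiked) / added)
}

#' Spike-recovery table
#'
#' Vectorized [recovery()] over a table of spike experiments, with a
#' presentation column rounded to 3 significant figures.
#'
#' @param table `data.frame` with columns `unspiked`, `spiked`, `added`
#'   (any extra columns, e.g. sample names, are carried through)
#' @return the input with `percentRecovery` (full precision) and
#'   `recovery3sf` (3 significant figures) appended
#' @export
recoveryTable <- function(table) {
  need <- c("unspiked", "spiked", "added")
  if (!all(need %in% names(table)))
    stop("recoveryTable: columns unspiked, spiked, added required")
  if (any(table$added <= 0))
    stop("recovery: amount added must be positive")
  table$percentRecovery <-
    100 * (table$spiked - table$unspiked) / table$added
  table$recovery3sf <- signif(table$percentRecovery, 3)
  table
}

#' Paired comparison of two measurement methods
#'
#' Two-sided paired t-test on per-sample differences (e.g. ethanol by
#' MIR-PLS against ethanol by GC-FID on the same beverages). When all
#' differences are exactly zero the methods are indistinguishable and the
#' test returns `p = 1`, non-significant, by convention.
#'
#' @param valuesA,valuesB paired measurements, equal length >= 3
#' @param alpha significance level (default 0.05, i.e. 95 % confidence)
#' @return list with `statistic` (t), `df`, `pValue`, `significant`,
#'   `meanDifference`
#' @export
pairedMethodComparison <- function(valuesA, valuesB, alpha = 0.05) {
  if (length(valuesA) != length(valuesB) || length(valuesA) < 3L)
    stop("pairedMethodComparison: need paired vectors of equal length >= 3")
  d <- valuesA - valuesB
  if (all(d == 0))
    return(list(statistic = 0, df = length(d) - 1L, pValue = 1,
                significant = FALSE, meanDifference = 0))
  if (stats::sd(d) == 0)
    # constant non-zero offset: infinitely strong evidence of a difference
    return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                pValue = 0, significant = TRUE, meanDifference = mean(d)))
  tt <- tryCatch(stats::t.test(valuesA, valuesB, paired = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # differences (nearly) constant but non-zero: t.test refuses; fall
    # back to the textbook statistic, which is then extreme
    n <- length(d)
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), n - 1)
    return(list(statistic = tstat, df = n - 1L, pValue = p,
                significant = p < alpha, meanDifference = mean(d)))
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, significant = tt$p.value < alpha,
       meanDifference = unname(tt$estimate))
}
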