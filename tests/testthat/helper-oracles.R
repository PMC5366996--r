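# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths they check.

# Savitzky-Golay derivative by direct per-window least-squares polynomial
# fits: interior points use the window centred on them; the first/last
# half-windows re-use the end windows and evaluate the fitted polynomial's
# derivative at the off-centre position.
sgOracle <- function(x, grid, order, window, polyorder) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  dx <- grid[2] - grid[1]
  derivAt <- function(idx, at) {
    t <- (grid[idx] - grid[at]) # local coordinate centred on target
    fit <- stats::lm.fit(outer(t, 0:polyorder, "^"), x[idx])
    cf <- fit$coefficients
    sum(vapply(order:polyorder, function(j)
      cf[j + 1] * factorial(j) / factorial(j - order) * 0^(j - order),
      0), na.rm = TRUE)
  }
  vapply(seq_len(n), function(i) {
    idx <- if (i <= h) 1:window
           else if (i > n - h) (n - window + 1L):n
           else (i - h):(i + h)
    derivAt(idx, i)
  }, 0)
}

# Minimum-norm least squares (with intercept) via SVD pseudo-inverse.
lsOracle <- function(X, y, newX = X) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  pos <- sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  b <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% (y - ym)) / sv$d[pos])
  drop(sweep(newX, 2, xm) %*% b) + ym
}

# Naive leave-one-out loop: rebuilds the pipeline and the model per fold
# from scratch through the public API, structured independently of looCV.
naiveLoo <- function(set, y, pipelineName, nLV) {
  n <- length(set)
  out <- numeric(n)
  for (i in seq_len(n)) {
    train <- set[setdiff(seq_len(n), i)]
    model <- fitPLS(train, y[-i], nLV, buildPipeline(pipelineName))
    out[i] <- unname(predict(model, set[i]))
  }
  sqrt(mean((out - y)^2))
}

# 0^(j-order) in sgOracle: 0^0 must be 1 (R convention), higher powers 0;
# only the j = order term survives, i.e. cf[order+1] * order!.

makeRandomSet <- function(n, grid, seed = 1) {
  set.seed(seed)
  SpectrumSet(matrix(stats::runif(n * length(grid)), n), grid)
}
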