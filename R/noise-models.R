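#' GE noise models
#'
#' Parametric models of the scatter of measurements about the prediction
#' \eqn{\hat{y} = g(\phi)} in global epistasis regression. Three families
#' are supported — Gaussian, Cauchy, and the skewed-t of Jones and Faddy
#' (which interpolates between them and accommodates asymmetric noise) —
#' plus an empirical Gaussian model with user-supplied per-measurement
#' standard errors and no free parameters. Each distribution parameter
#' (the scale \eqn{s}; also the skew-t shape parameters \eqn{a, b}) is an
#' exponentiated K-order polynomial in \eqn{\hat{y}} with K+1 trainable
#' coefficients, so all families may be heteroscedastic; K = 0 gives a
#' constant (homoscedastic) parameter.
#'
#' @slot coeffs polynomial coefficients \eqn{a_0..a_K} of \eqn{\log s}.
#' @slot sCoeffs,aCoeffs,bCoeffs skew-t coefficient sets for s, a, b.
#' @name NoiseModel-class
#' @aliases NoiseModel
#' @export
setClass("NoiseModel", representation("VIRTUAL"))

#' @rdname NoiseModel-class
#' @export
setClass("GaussianNoise", contains = "NoiseModel",
  representation(coeffs = "numeric"))

#' @rdname NoiseModel-class
#' @export
setClass("CauchyNoise", contains = "NoiseModel",
  representation(coeffs = "numeric"))

#' @rdname NoiseModel-class
#' @export
setClass("SkewTNoise", contains = "NoiseModel",
  representation(sCoeffs = "numeric", aCoeffs = "numeric",
                 bCoeffs = "numeric"))

#' @rdname NoiseModel-class
#' @export
setClass("EmpiricalNoise", contains = "NoiseModel")

#' Construct GE noise models
#'
#' @param coeffs,sCoeffs,aCoeffs,bCoeffs polynomial coefficients of the
#'   log of the corresponding distribution parameter; the polynomial order
#'   K equals \code{length(coeffs) - 1}.
#' @return A \linkS4class{NoiseModel} of the requested family.
#' @examples
#' gaussianNoise(log(2))          # homoscedastic, s = 2
#' skewTNoise(0, log(2), log(3))  # s = 1, a = 2, b = 3
#' @export
gaussianNoise <- function(coeffs = 0) new("GaussianNoise", coeffs = coeffs)

#' @rdname gaussianNoise
#' @export
cauchyNoise <- function(coeffs = 0) new("CauchyNoise", coeffs = coeffs)

#' @rdname gaussianNoise
#' @export
skewTNoise <- function(sCoeffs = 0, aCoeffs = 0, bCoeffs = 0)
  new("SkewTNoise", sCoeffs = sCoeffs, aCoeffs = aCoeffs, bCoeffs = bCoeffs)

#' @rdname gaussianNoise
#' @export
empiricalNoise <- function() new("EmpiricalNoise")

#' Heteroscedastic noise scale
#'
#' Evaluates \eqn{s(\hat{y}) = \exp[\sum_{k=0}^{K} a_k \hat{y}^k]}, always
#' positive; the exponent is clipped to [-30, 30] to guard overflow.
#'
#' @param yhat prediction values.
#' @param coeffs polynomial coefficients \eqn{a_0..a_K}.
#' @return Positive numeric vector of scales.
#' @examples
#' noiseScale(-1, c(0, 1))  # exp(-1)
#' @export
noiseScale <- function(yhat, coeffs) {
  K <- length(coeffs) - 1L
  z <- rep(coeffs[1L], length(yhat))
  if (K >= 1L) for (k in seq_len(K)) z <- z + coeffs[k + 1L] * yhat^k
  exp(pmin(pmax(z, -30), 30))
}

.skewt_params <- function(noise, yhat) {
  list(s = noiseScale(yhat, noise@sCoeffs),
       a = noiseScale(yhat, noise@aCoeffs),
       b = noiseScale(yhat, noise@bCoeffs))
}

# mode-offset statistic of the Jones-Faddy skewed-t
.skewt_tstar <- function(a, b)
  (a - b) * sqrt(a + b) / (sqrt(2 * a + 1) * sqrt(2 * b + 1))

# log density of the standardized skew-t variate t
.skewt_logf <- function(t, a, b) {
  r <- sqrt(a + b + t^2)
  u <- t / r  # in (-1, 1)
  (1 - a - b) * log(2) - 0.5 * log(a + b) +
    lgamma(a + b) - lgamma(a) - lgamma(b) +
    (a + 0.5) * log1p(u) + (b + 0.5) * log1p(-u)
}

#' Noise model log density, quantiles, CDF and sampling
#'
#' All operations are vectorized over observations and evaluated at the
#' (possibly \eqn{\hat{y}}-dependent) distribution parameters. Quantiles
#' invert the CDF exactly: Gaussian via the probit, Cauchy via
#' \eqn{\hat{y} + s\tan[\pi(q - 1/2)]}, skew-t via the inverse regularized
#' incomplete beta function. The skew-t is parameterized so its mode sits
#' exactly at \eqn{\hat{y}}.
#'
#' @param noise a \linkS4class{NoiseModel}.
#' @param y observed measurements.
#' @param yhat predictions \eqn{g(\phi)}.
#' @param q quantile levels in (0, 1).
#' @param se per-measurement standard errors (empirical noise only).
#' @return \code{noiseLogPdf}: log densities; \code{noiseQuantile}:
#'   measurement quantiles; \code{noiseCdf}: distribution function;
#'   \code{noiseSample}: random measurements.
#' @export
setGeneric("noiseLogPdf",
  function(noise, y, yhat, se = NULL) standardGeneric("noiseLogPdf"))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseLogPdf", "GaussianNoise", function(noise, y, yhat, se) {
  s <- noiseScale(yhat, noise@coeffs)
  stats::dnorm(y, yhat, s, log = TRUE)
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseLogPdf", "CauchyNoise", function(noise, y, yhat, se) {
  s <- noiseScale(yhat, noise@coeffs)
  stats::dcauchy(y, yhat, s, log = TRUE)
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseLogPdf", "SkewTNoise", function(noise, y, yhat, se) {
  p <- .skewt_params(noise, yhat)
  t <- .skewt_tstar(p$a, p$b) + (y - yhat) / p$s
  .skewt_logf(t, p$a, p$b) - log(p$s)
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseLogPdf", "EmpiricalNoise", function(noise, y, yhat, se) {
  if (is.null(se) || !length(se))
    stop("empirical noise model requires per-measurement standard errors")
  stats::dnorm(y, yhat, se, log = TRUE)
})

#' @rdname noiseLogPdf
#' @export
setGeneric("noiseQuantile",
  function(noise, q, yhat, se = NULL) standardGeneric("noiseQuantile"))

.check_q <- function(q) {
  if (any(q <= 0 | q >= 1)) stop("quantile levels must lie in (0, 1)")
}

#' @rdname noiseLogPdf
#' @export
setMethod("noiseQuantile", "GaussianNoise", function(noise, q, yhat, se) {
  .check_q(q)
  stats::qnorm(q, yhat, noiseScale(yhat, noise@coeffs))
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseQuantile", "CauchyNoise", function(noise, q, yhat, se) {
  .check_q(q)
  yhat + noiseScale(yhat, noise@coeffs) * tan(pi * (q - 0.5))
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseQuantile", "SkewTNoise", function(noise, q, yhat, se) {
  .check_q(q)
  p <- .skewt_params(noise, yhat)
  xq <- stats::qbeta(q, p$a, p$b)
  u <- 2 * xq - 1
  tq <- u * sqrt(p$a + p$b) / sqrt(pmax(1 - u^2, .Machine$double.eps))
  yhat + (tq - .skewt_tstar(p$a, p$b)) * p$s
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseQuantile", "EmpiricalNoise", function(noise, q, yhat, se) {
  .check_q(q)
  if (is.null(se)) stop("empirical noise quantiles need 'se'")
  stats::qnorm(q, yhat, se)
})

#' @rdname noiseLogPdf
#' @export
setGeneric("noiseCdf",
  function(noise, y, yhat, se = NULL) standardGeneric("noiseCdf"))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseCdf", "GaussianNoise", function(noise, y, yhat, se)
  stats::pnorm(y, yhat, noiseScale(yhat, noise@coeffs)))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseCdf", "CauchyNoise", function(noise, y, yhat, se)
  stats::pcauchy(y, yhat, noiseScale(yhat, noise@coeffs)))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseCdf", "SkewTNoise", function(noise, y, yhat, se) {
  p <- .skewt_params(noise, yhat)
  t <- .skewt_tstar(p$a, p$b) + (y - yhat) / p$s
  x <- 0.5 * (1 + t / sqrt(p$a + p$b + t^2))
  stats::pbeta(x, p$a, p$b)
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseCdf", "EmpiricalNoise", function(noise, y, yhat, se)
  stats::pnorm(y, yhat, se))

#' @rdname noiseLogPdf
#' @export
setGeneric("noiseSample",
  function(noise, yhat, se = NULL) standardGeneric("noiseSample"))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseSample", "GaussianNoise", function(noise, yhat, se)
  stats::rnorm(length(yhat), yhat, noiseScale(yhat, noise@coeffs)))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseSample", "CauchyNoise", function(noise, yhat, se)
  stats::rcauchy(length(yhat), yhat, noiseScale(yhat, noise@coeffs)))

#' @rdname noiseLogPdf
#' @export
setMethod("noiseSample", "SkewTNoise", function(noise, yhat, se) {
  p <- .skewt_params(noise, yhat)
  x <- stats::rbeta(length(yhat), p$a, p$b)
  u <- pmin(pmax(2 * x - 1, -1 + 1e-12), 1 - 1e-12)
  t <- u * sqrt(p$a + p$b) / sqrt(1 - u^2)
  yhat + (t - .skewt_tstar(p$a, p$b)) * p$s
})

#' @rdname noiseLogPdf
#' @export
setMethod("noiseSample", "EmpiricalNoise", function(noise, yhat, se) {
  if (is.null(se)) stop("empirical noise sampling needs 'se'")
  stats::rnorm(length(yhat), yhat, se)
})
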