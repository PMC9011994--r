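#' GE nonlinearity (sum of hyperbolic-tangent sigmoids)
#'
#' The global-epistasis measurement process maps the latent phenotype to
#' the most-probable measurement through
#' \deqn{g(\phi; \alpha) = a + \sum_{k=0}^{K-1} b_k \tanh(c_k \phi + d_k),}
#' a flexible bottleneck parameterization. When \code{monotonic} is set
#' (the default during fitting), all \eqn{b_k \ge 0} and \eqn{c_k \ge 0},
#' which makes \eqn{g} non-decreasing in \eqn{\phi}.
#'
#' The degenerate \code{kind = "linear"} variant, \eqn{g(\phi) = a +
#' b_1\phi}, is used when the assayed library contains only
#' single-mutation variants, where nonlinearities are unidentifiable.
#'
#' @slot a scalar offset.
#' @slot b,c,d per-node amplitude, slope and shift, each of length K.
#' @slot monotonic whether the nonnegativity constraint is in force.
#' @slot kind "tanh" (sum of sigmoids) or "linear" (affine; b holds the
#'   slope, c and d are unused).
#' @export
setClass("GENonlinearity",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 monotonic = "logical", kind = "character"))

setValidity("GENonlinearity", function(object) {
  K <- length(object@b)
  if (length(object@c) != K || length(object@d) != K)
    return("b, c, d must have equal length K")
  if (K < 1L) return("need at least one hidden node")
  if (!object@kind %in% c("tanh", "linear"))
    return("kind must be 'tanh' or 'linear'")
  if (object@kind == "tanh" && object@monotonic &&
      (any(object@b < 0) || any(object@c < 0)))
    return("monotonic nonlinearity requires b_k >= 0 and c_k >= 0")
  TRUE
})

#' Construct a GE nonlinearity
#'
#' @param a scalar offset.
#' @param b,c,d numeric vectors of per-node parameters (equal length K).
#' @param monotonic enforce \eqn{b_k, c_k \ge 0}.
#' @param kind "tanh" or "linear" (see \linkS4class{GENonlinearity}).
#' @return A \linkS4class{GENonlinearity}.
#' @examples
#' g <- geNonlinearity(0, 1, 1, 0)
#' evalNonlinearity(g, 0)  # tanh(0) = 0
#' @export
geNonlinearity <- function(a = 0, b = 1, c = 1, d = 0, monotonic = TRUE,
                           kind = "tanh") {
  if (kind == "linear") { c <- numeric(length(b)); d <- numeric(length(b)) }
  new("GENonlinearity", a = a, b = b, c = c, d = d, monotonic = monotonic,
      kind = kind)
}

#' Evaluate a GE nonlinearity
#'
#' @param nonlin a \linkS4class{GENonlinearity}.
#' @param phiVals latent phenotype values.
#' @return Predictions \eqn{\hat{y} = g(\phi)}, finite and (when
#'   monotonic) non-decreasing in \eqn{\phi}.
#' @export
evalNonlinearity <- function(nonlin, phiVals) {
  if (nonlin@kind == "linear")
    return(nonlin@a + nonlin@b[1] * phiVals)
  out <- rep(nonlin@a, length(phiVals))
  for (k in seq_along(nonlin@b))
    out <- out + nonlin@b[k] * tanh(nonlin@c[k] * phiVals + nonlin@d[k])
  out
}

# derivative dg/dphi
.ge_gprime <- function(nonlin, phiVals) {
  if (nonlin@kind == "linear")
    return(rep(nonlin@b[1], length(phiVals)))
  out <- numeric(length(phiVals))
  for (k in seq_along(nonlin@b)) {
    th <- tanh(nonlin@c[k] * phiVals + nonlin@d[k])
    out <- out + nonlin@b[k] * nonlin@c[k] * (1 - th^2)
  }
  out
}

#' GE measurement process
#'
#' Couples a monotonic nonlinearity \eqn{g(\phi)} with a noise model
#' \eqn{p(y|\hat{y})}; together they define \eqn{p(y|\phi)} for continuous
#' measurements.
#'
#' @slot nonlin a \linkS4class{GENonlinearity}.
#' @slot noise a \linkS4class{NoiseModel}.
#' @export
setClass("GEMeasurement",
  representation(nonlin = "GENonlinearity", noise = "NoiseModel"))

#' @rdname GEMeasurement-class
#' @param nonlin a \linkS4class{GENonlinearity}.
#' @param noise a \linkS4class{NoiseModel}.
#' @export
geMeasurement <- function(nonlin, noise = gaussianNoise())
  new("GEMeasurement", nonlin = nonlin, noise = noise)

setMethod("show", "GEMeasurement", function(object) {
  cat("GE measurement process: K =", length(object@nonlin@b),
      "tanh nodes,", if (object@nonlin@monotonic) "monotonic,",
      "noise:", class(object@noise), "\n")
})

#' Prediction intervals of a GE measurement process
#'
#' Interval between two noise-model quantiles at \eqn{\hat{y} = g(\phi)},
#' e.g. (0.025, 0.975) for the 95\% PI.
#'
#' @param measurement a \linkS4class{GEMeasurement}.
#' @param phiVals latent phenotype values.
#' @param qLo,qHi lower and upper quantile levels, \code{qLo < qHi}.
#' @param se per-measurement standard errors, required for the empirical
#'   noise model.
#' @return A data.frame with columns \code{phi}, \code{yhat}, \code{yLo},
#'   \code{yHi}.
#' @export
predictionInterval <- function(measurement, phiVals, qLo = 0.025,
                               qHi = 0.975, se = NULL) {
  stopifnot(qLo < qHi)
  if (is(measurement@noise, "EmpiricalNoise") && is.null(se))
    stop("prediction intervals under empirical noise need 'se' for the ",
         "query points")
  yhat <- evalNonlinearity(measurement@nonlin, phiVals)
  data.frame(phi = phiVals, yhat = yhat,
             yLo = noiseQuantile(measurement@noise, qLo, yhat, se),
             yHi = noiseQuantile(measurement@noise, qHi, yhat, se))
}
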