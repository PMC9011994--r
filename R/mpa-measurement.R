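#' MPA measurement process
#'
#' Measurement-process-agnostic model for discrete (binned) readouts: a
#' one-hidden-layer perceptron per bin with tanh activations and a softmax
#' output,
#' \deqn{p(y|\phi) = \frac{w_y(\phi)}{\sum_{y'} w_{y'}(\phi)}, \quad
#'       w_y(\phi) = \exp\left[a_y + \sum_{k=0}^{K-1} b_{yk}
#'       \tanh(c_{yk}\phi + d_{yk})\right].}
#' Probabilities are positive and sum to 1; adding a constant to every
#' \eqn{a_y} leaves them unchanged.
#'
#' @slot a per-bin offsets, length Y >= 2.
#' @slot b,c,d Y x K matrices of per-bin per-node parameters, K >= 1.
#' @export
setClass("MPAMeasurement",
  representation(a = "numeric", b = "matrix", c = "matrix", d = "matrix"))

setValidity("MPAMeasurement", function(object) {
  Y <- length(object@a)
  if (Y < 2L) return("need Y >= 2 bins")
  dims <- lapply(list(object@b, object@c, object@d), dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    return("b, c, d must have identical Y x K dimensions")
  if (nrow(object@b) != Y) return("b, c, d must have Y rows")
  if (ncol(object@b) < 1L) return("need K >= 1 hidden nodes per bin")
  TRUE
})

#' Construct an MPA measurement process
#'
#' @param Y number of bins.
#' @param K hidden nodes per bin (default 10).
#' @param a optional per-bin offsets (default 0).
#' @param b,c,d optional Y x K parameter matrices (default 0, giving the
#'   uniform process \eqn{p(y|\phi) = 1/Y}).
#' @return An \linkS4class{MPAMeasurement}.
#' @examples
#' m <- mpaMeasurement(Y = 2, K = 1, a = c(0, log(3)))
#' mpaProbabilities(m, 0)  # 0.25, 0.75
#' @export
mpaMeasurement <- function(Y, K = 10L, a = NULL, b = NULL, c = NULL,
                           d = NULL) {
  zero <- matrix(0, Y, K)
  new("MPAMeasurement",
      a = if (is.null(a)) numeric(Y) else a,
      b = if (is.null(b)) zero else b,
      c = if (is.null(c)) zero else c,
      d = if (is.null(d)) zero else d)
}

setMethod("show", "MPAMeasurement", function(object) {
  cat("MPA measurement process: Y =", length(object@a), "bins, K =",
      ncol(object@b), "hidden nodes per bin\n")
})

#' Bin probabilities under an MPA measurement process
#'
#' @param measurement an \linkS4class{MPAMeasurement}.
#' @param phiVals latent phenotype values.
#' @return Matrix of probabilities with one row per phi value and Y
#'   columns; rows sum to 1.
#' @export
mpaProbabilities <- function(measurement, phiVals) {
  logw <- .mpa_logw(measurement, phiVals)
  m <- apply(logw, 1, max)
  w <- exp(logw - m)
  w / rowSums(w)
}

# n x Y matrix of log weights log w_y(phi)
.mpa_logw <- function(measurement, phiVals) {
  Y <- length(measurement@a); K <- ncol(measurement@b)
  n <- length(phiVals)
  logw <- matrix(rep(measurement@a, each = n), n, Y)
  for (y in seq_len(Y)) for (k in seq_len(K)) {
    logw[, y] <- logw[, y] + measurement@b[y, k] *
      tanh(measurement@c[y, k] * phiVals + measurement@d[y, k])
  }
  logw
}
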