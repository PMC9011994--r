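#' Negative log likelihood of a latent model on a dataset
#'
#' \eqn{L_{like} = -\sum_n \ln p(y_n|\phi_n)} for sequence-measurement
#' pairs, or \eqn{-\sum_m \sum_y c_{my} \ln p(y|\phi_m)} for count-matrix
#' data; the two forms agree exactly on equivalent data. Reported in nats.
#' Zero-probability observations contribute a large finite penalty (log
#' clipped at -690) with a warning instead of an infinite loss.
#'
#' @param model a \linkS4class{LatentModel} whose mode matches the dataset
#'   (GE for continuous y, MPA for bins/counts).
#' @param dataset a \linkS4class{MaveDataset}.
#' @return Scalar negative log likelihood (nats).
#' @export
negativeLogLikelihood <- function(model, dataset) {
  mode <- datasetMode(dataset)
  isGE <- is(model@measurement, "GEMeasurement")
  if (isGE != (mode == "ge"))
    stop("model type (", if (isGE) "GE" else "MPA",
         ") does not match dataset mode '", mode, "'")
  phiVals <- phi(model@gpmap, dataset@sequences)
  if (anyNA(phiVals)) stop("phi undefined (NA) for some sequences")
  if (isGE) {
    yhat <- evalNonlinearity(model@measurement@nonlin, phiVals)
    ll <- noiseLogPdf(model@measurement@noise, dataset@y, yhat,
                      se = dataset@se)
  } else if (mode == "mpa_bins") {
    P <- mpaProbabilities(model@measurement, phiVals)
    if (max(dataset@bins) + 1L > ncol(P)) stop("bin label exceeds model Y")
    ll <- log(P[cbind(seq_along(phiVals), dataset@bins + 1L)])
  } else {
    P <- mpaProbabilities(model@measurement, phiVals)
    if (ncol(dataset@counts) != ncol(P))
      stop("count matrix has ", ncol(dataset@counts),
           " bins but model has ", ncol(P))
    return(-.clipped_sum(log(P) * dataset@counts))
  }
  -.clipped_sum(ll)
}

.clipped_sum <- function(ll) {
  bad <- which(!is.finite(ll) | ll < -690)
  if (length(bad)) {
    warning(length(bad), " observation(s) had (near-)zero probability; ",
            "log clipped at -690")
    ll[bad] <- -690
  }
  sum(ll)
}

#' L2 regularization penalty
#'
#' \eqn{L_{reg} = \lambda_\theta \|\theta\|^2 + \lambda_\eta \|\eta\|^2},
#' where \eqn{\theta} are G-P map parameters and \eqn{\eta} measurement
#' process parameters (all of them, including offsets).
#'
#' @param theta numeric vector of G-P map parameters.
#' @param eta numeric vector of measurement-process parameters.
#' @param lambdaTheta,lambdaEta nonnegative penalty weights (defaults
#'   1e-3 and 1e-1).
#' @return Scalar penalty.
#' @examples
#' l2Penalty(c(3, 4), numeric(0), lambdaTheta = 1)  # 25
#' @export
l2Penalty <- function(theta, eta = numeric(0), lambdaTheta = 1e-3,
                      lambdaEta = 1e-1) {
  stopifnot(lambdaTheta >= 0, lambdaEta >= 0)
  lambdaTheta * sum(theta^2) + lambdaEta * sum(eta^2)
}
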