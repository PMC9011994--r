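setClassUnion("Measurement", c("GEMeasurement", "MPAMeasurement"))

#' Latent phenotype model
#'
#' A full probabilistic model \eqn{p(y|x)}: a deterministic G-P map
#' assigning each sequence a latent phenotype, composed with a stochastic
#' measurement process (GE regression for continuous y, MPA regression for
#' binned y). Produced by \code{\link{fitLatentModel}} or assembled by
#' hand (e.g. as a simulation ground truth).
#'
#' @slot gpmap a \linkS4class{GPMap}.
#' @slot measurement a \linkS4class{GEMeasurement} or
#'   \linkS4class{MPAMeasurement}.
#' @slot diffeo centering constants (a, b) applied by
#'   \code{\link{fixDiffeomorphic}} (empty if not yet fixed).
#' @slot gauge name of the gauge distribution used for hierarchical gauge
#'   fixing ("none" for custom/black-box maps).
#' @slot history per-epoch training history (loss, validation loss,
#'   variational information in bits).
#' @slot split list of train/validation/test row indices.
#' @slot config fitting configuration actually used.
#' @export
setClass("LatentModel",
  representation(gpmap = "GPMap", measurement = "Measurement",
                 diffeo = "numeric", gauge = "character",
                 history = "data.frame", split = "list", config = "list"))

#' Assemble a latent phenotype model
#'
#' @param gpmap a \linkS4class{GPMap}.
#' @param measurement a measurement process.
#' @param gauge gauge label to record (default "none").
#' @return A \linkS4class{LatentModel}.
#' @export
latentModel <- function(gpmap, measurement, gauge = "none") {
  new("LatentModel", gpmap = gpmap, measurement = measurement,
      diffeo = numeric(0), gauge = gauge,
      history = data.frame(), split = list(), config = list())
}

setMethod("show", "LatentModel", function(object) {
  cat("LatentModel (",
      if (is(object@measurement, "GEMeasurement")) "GE regression"
      else "MPA regression", ")\n", sep = "")
  show(object@gpmap)
  show(object@measurement)
  if (length(object@diffeo))
    cat("  diffeomorphic fix: a =", signif(object@diffeo["a"], 4),
        ", b =", signif(object@diffeo["b"], 4), "\n")
  cat("  gauge:", object@gauge, "\n")
})

#' @rdname phi
#' @export
setMethod("phi", "LatentModel", function(map, sequences)
  phi(map@gpmap, sequences))

#' Model predictions
#'
#' \code{predictYhat} returns the most-probable measurement
#' \eqn{\hat{y} = g(\phi(x))} of a GE model; \code{predictBinProbs}
#' returns the bin probability matrix \eqn{p(y|\phi(x))} of an MPA model.
#'
#' @param model a \linkS4class{LatentModel}.
#' @param sequences character vector of sequences.
#' @return Numeric vector (\code{predictYhat}) or matrix with Y columns
#'   (\code{predictBinProbs}).
#' @export
predictYhat <- function(model, sequences) {
  stopifnot(is(model@measurement, "GEMeasurement"))
  evalNonlinearity(model@measurement@nonlin, phi(model@gpmap, sequences))
}

#' @rdname predictYhat
#' @export
predictBinProbs <- function(model, sequences) {
  stopifnot(is(model@measurement, "MPAMeasurement"))
  mpaProbabilities(model@measurement, phi(model@gpmap, sequences))
}
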