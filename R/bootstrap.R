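#' Parametric bootstrap result
#'
#' @slot se per-parameter standard errors (gauge-fixed scale).
#' @slot replicates R x P matrix of gauge-fixed replicate parameter
#'   vectors.
#' @slot paramNames parameter labels.
#' @export
setClass("BootstrapResult",
  representation(se = "numeric", replicates = "matrix",
                 paramNames = "character"))

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult:", nrow(object@replicates), "replicates,",
      length(object@se), "parameters; median SE =",
      signif(stats::median(object@se, na.rm = TRUE), 3), "\n")
})

#' @rdname parametricBootstrap
#' @param x a \linkS4class{BootstrapResult}.
#' @export
bootstrapSE <- function(x) stats::setNames(x@se, x@paramNames)

#' Parametric bootstrap uncertainties for G-P map parameters
#'
#' Treats the trained model as ground truth: the assayed sequences are
#' held fixed, R replicate datasets are simulated from the model's own
#' measurement process, and a model is refit to each (reusing the
#' original hyperparameters, with refits initialized at the trained
#' parameter values and per-replicate seeds derived from \code{seed}).
#' Every refit is gauge-fixed in the same gauge as the input model before
#' aggregation, so gauge and diffeomorphic freedom does not inflate the
#' spread, and \eqn{\delta\theta_k = \mathrm{std}(\{\theta_k^{(r)}\})}.
#' Black-box maps are rejected: individual parameter uncertainties are
#' not meaningful for heavily overparameterized models. Custom maps are
#' accepted with a warning that their gauge freedoms are the user's
#' responsibility.
#'
#' @param model a fitted \linkS4class{LatentModel} (parametric or custom
#'   G-P map).
#' @param sequences the assayed sequences to keep fixed (defaults to
#'   regenerating measurements for the model's own training sequences is
#'   not possible, so this argument is required).
#' @param R number of simulate-and-refit cycles (default 25).
#' @param seed master seed; replicate r uses seed + r.
#' @param reads reads per sequence for MPA count simulation.
#' @param se per-measurement standard errors (empirical noise).
#' @param ... overrides passed to \code{\link{fitLatentModel}} (e.g.
#'   epochs).
#' @return A \linkS4class{BootstrapResult}.
#' @export
parametricBootstrap <- function(model, sequences, R = 25L, seed = 1L,
                                reads = NULL, se = NULL, ...) {
  gp <- model@gpmap
  if (is(gp, "BlackBoxGPMap"))
    stop("parametric bootstrap is rejected for black-box G-P maps: no ",
         "meaningful per-parameter uncertainties exist for highly ",
         "overparameterized models")
  isCustom <- is(gp, "CustomGPMap")
  if (isCustom)
    warning("custom G-P maps are not gauge-fixed automatically; ensure ",
            "the map's own gauge freedoms are fixed before interpreting ",
            "parameter uncertainties")
  cfg <- model@config
  if (!length(cfg))
    cfg <- list(gpmap = if (isCustom) "custom" else "additive",
                noise = "gaussian", gauge = "uniform", wildtype = NULL)
  overrides <- list(...)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    sim <- simulateDataset(model, sequences, reads = reads, se = se,
                           seed = seed + r)
    args <- list(dataset = sim,
      gpmap = if (isCustom) gp else cfg$gpmap,
      noise = if (!is.null(cfg$noise)) cfg$noise else "gaussian",
      seed = seed + r)
    for (nm in c("K", "mpaK", "polyOrder", "lambdaTheta", "lambdaEta",
                 "split", "epochs", "batchSize", "learnRate", "patience",
                 "gauge", "monotonic", "linearNonlin"))
      if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
    if (!is.null(cfg$wildtype)) args$wildtype <- cfg$wildtype
    args[names(overrides)] <- overrides
    fitR <- do.call(fitLatentModel, args)
    reps[[r]] <- if (isCustom) unname(fitR@gpmap@params)
                 else .gp_pack(fitR@gpmap)
  }
  M <- do.call(rbind, reps)
  nm <- if (isCustom) names(gp@params)
        else c("theta0", as.vector(t(outer(0:(gp@L - 1L),
               gp@alphabet@characters, paste, sep = ":"))),
               if (is(gp, "NeighborGPMap") && length(gp@thetaPairs))
                 paste0("pair", seq_along(gp@thetaPairs)))
  new("BootstrapResult", se = apply(M, 2, stats::sd),
      replicates = M, paramNames = nm)
}
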