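#' Save / load a model bundle
#'
#' Serializes a \linkS4class{LatentModel} to a single documented JSON
#' container: the G-P map kind, alphabet and parameters; the measurement
#' process (GE nonlinearity and noise coefficients, or MPA softmax
#' parameters); the diffeomorphic constants and gauge choice (so exported
#' parameters are reproducible); and the fitting configuration. Additive,
#' neighbor, pairwise and black-box maps round-trip exactly. Custom maps
#' are not serializable (their phi function is arbitrary R code); save
#' their parameter vector instead.
#'
#' @param model a \linkS4class{LatentModel}.
#' @param path output JSON path.
#' @return \code{readModelBundle}: the reconstructed
#'   \linkS4class{LatentModel}.
#' @export
writeModelBundle <- function(model, path) {
  gp <- model@gpmap
  if (is(gp, "CustomGPMap"))
    stop("custom G-P maps cannot be serialized to a bundle; save ",
         "their parameters (gp@params) instead")
  gpRec <- if (is(gp, "AdditiveGPMap")) {
    list(kind = if (is(gp, "PairwiseGPMap")) "pairwise"
           else if (is(gp, "NeighborGPMap")) "neighbor" else "additive",
         L = gp@L, alphabet = paste(gp@alphabet@characters, collapse = ""),
         alphabetName = gp@alphabet@name,
         theta0 = gp@theta0, thetaLC = as.vector(t(gp@thetaLC)),
         thetaPairs = if (is(gp, "NeighborGPMap")) gp@thetaPairs
                      else numeric(0))
  } else {
    list(kind = "blackbox", L = gp@L,
         alphabet = paste(gp@alphabet@characters, collapse = ""),
         alphabetName = gp@alphabet@name,
         hidden = gp@hidden, activation = gp@activation,
         inputFeatures = gp@inputFeatures,
         weights = .mlp_pack(gp@weights))
  }
  meas <- model@measurement
  measRec <- if (is(meas, "GEMeasurement")) {
    nz <- meas@noise
    list(process = "ge",
         nonlin = list(a = meas@nonlin@a, b = meas@nonlin@b,
                       c = meas@nonlin@c, d = meas@nonlin@d,
                       monotonic = meas@nonlin@monotonic,
                       kind = meas@nonlin@kind),
         noise = switch(class(nz),
           GaussianNoise = list(family = "gaussian", coeffs = nz@coeffs),
           CauchyNoise = list(family = "cauchy", coeffs = nz@coeffs),
           SkewTNoise = list(family = "skewt", sCoeffs = nz@sCoeffs,
                             aCoeffs = nz@aCoeffs, bCoeffs = nz@bCoeffs),
           EmpiricalNoise = list(family = "empirical")))
  } else {
    list(process = "mpa", a = meas@a, b = as.vector(meas@b),
         c = as.vector(meas@c), d = as.vector(meas@d),
         Y = length(meas@a), K = ncol(meas@b))
  }
  bundle <- list(format = "latentmave-bundle", version = 1L,
                 gpmap = gpRec, measurement = measRec,
                 diffeo = as.list(model@diffeo), gauge = model@gauge,
                 config = model@config[!vapply(model@config, is.null, TRUE)])
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeModelBundle
#' @export
readModelBundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "latentmave-bundle"))
    stop("not a latentmave model bundle")
  alph <- Alphabet(b$gpmap$alphabet, name = b$gpmap$alphabetName)
  L <- b$gpmap$L
  gp <- switch(b$gpmap$kind,
    additive = .gp_unpack(additiveGPMap(L, alph),
                          c(b$gpmap$theta0, b$gpmap$thetaLC)),
    neighbor = .gp_unpack(neighborGPMap(L, alph),
                          c(b$gpmap$theta0, b$gpmap$thetaLC,
                            b$gpmap$thetaPairs)),
    pairwise = .gp_unpack(pairwiseGPMap(L, alph),
                          c(b$gpmap$theta0, b$gpmap$thetaLC,
                            b$gpmap$thetaPairs)),
    blackbox = {
      g <- blackboxGPMap(L, alph, hidden = b$gpmap$hidden,
                         inputFeatures = b$gpmap$inputFeatures,
                         activation = b$gpmap$activation)
      g@weights <- .mlp_unpack(g@weights, b$gpmap$weights)
      g
    })
  meas <- if (b$measurement$process == "ge") {
    nl <- b$measurement$nonlin
    nz <- b$measurement$noise
    geMeasurement(
      new("GENonlinearity", a = nl$a, b = nl$b, c = nl$c, d = nl$d,
          monotonic = nl$monotonic, kind = nl$kind),
      switch(nz$family,
        gaussian = gaussianNoise(nz$coeffs),
        cauchy = cauchyNoise(nz$coeffs),
        skewt = skewTNoise(nz$sCoeffs, nz$aCoeffs, nz$bCoeffs),
        empirical = empiricalNoise()))
  } else {
    m <- b$measurement
    mpaMeasurement(m$Y, m$K, a = m$a,
                   b = matrix(m$b, m$Y, m$K),
                   c = matrix(m$c, m$Y, m$K),
                   d = matrix(m$d, m$Y, m$K))
  }
  model <- latentModel(gp, meas, gauge = b$gauge)
  if (length(b$diffeo)) model@diffeo <- unlist(b$diffeo)
  if (length(b$config)) model@config <- b$config
  model
}
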