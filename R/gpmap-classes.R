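#' Genotype-phenotype maps
#'
#' A G-P map deterministically assigns a scalar latent phenotype
#' \eqn{\phi(x)} to each fixed-length sequence. Built-in parametric maps:
#' \describe{
#'   \item{additive}{\eqn{\phi = \theta_0 + \sum_{l,c} \theta_{l:c} x_{l:c}}}
#'   \item{neighbor}{additive plus interactions between adjacent positions
#'     \eqn{\theta_{l:c,(l+1):c'}}}
#'   \item{pairwise}{additive plus interactions between all position pairs
#'     \eqn{\theta_{l:c,l':c'}} with \eqn{l' > l}}
#' }
#' plus a multilayer-perceptron map (\linkS4class{BlackBoxGPMap}) and a
#' custom-map contract (\linkS4class{CustomGPMap}) for, e.g., thermodynamic
#' models. Additive effects for (position, character) combinations never
#' observed in training are stored as \code{NA}; latent phenotypes of
#' sequences touching them are returned as \code{NA} rather than silently
#' computed.
#'
#' @slot L sequence length.
#' @slot C alphabet size.
#' @slot alphabet the \linkS4class{Alphabet}.
#' @name GPMap-class
#' @aliases GPMap
#' @export
setClass("GPMap",
  representation("VIRTUAL", L = "integer", nchars = "integer",
                 alphabet = "Alphabet"))

#' @rdname GPMap-class
#' @slot theta0 scalar constant.
#' @slot thetaLC L x C matrix of additive effects (rows = positions,
#'   columns = alphabet order; may contain \code{NA}).
#' @export
setClass("AdditiveGPMap", contains = "GPMap",
  representation(theta0 = "numeric", thetaLC = "matrix"))

#' @rdname GPMap-class
#' @slot thetaPairs flat numeric vector of interaction effects, ordered by
#'   position pair (l, l') with l' > l, then row-major by (c, c') —
#'   matching \code{\link{pairwiseFeatures}} columns.
#' @slot pairs integer matrix of 0-based (l, l') pairs.
#' @export
setClass("NeighborGPMap", contains = "AdditiveGPMap",
  representation(thetaPairs = "numeric", pairs = "matrix"))

#' @rdname GPMap-class
#' @export
setClass("PairwiseGPMap", contains = "NeighborGPMap")

setValidity("AdditiveGPMap", function(object) {
  if (length(object@theta0) != 1L) return("theta0 must be a scalar")
  if (!identical(dim(object@thetaLC),
                 c(as.integer(object@L), as.integer(object@nchars))))
    return("thetaLC must be an L x C matrix")
  TRUE
})

setValidity("NeighborGPMap", function(object) {
  want <- nrow(object@pairs) * object@nchars^2
  if (length(object@thetaPairs) != want)
    return(sprintf("thetaPairs must have %d entries", want))
  if (nrow(object@pairs) > 0L &&
      !all(object@pairs[, 2] > object@pairs[, 1]))
    return("interaction pairs must satisfy l' > l")
  TRUE
})

setValidity("PairwiseGPMap", function(object) {
  if (nrow(object@pairs) != object@L * (object@L - 1L) / 2L)
    return("pairwise map must cover all position pairs")
  TRUE
})

#' Construct parametric G-P maps
#'
#' @param L sequence length.
#' @param alphabet an \linkS4class{Alphabet}.
#' @param theta0 scalar constant (default 0).
#' @param thetaLC L x C additive-effect matrix (default all 0).
#' @param thetaPairs flat interaction vector (default all 0); ordering as
#'   documented in \linkS4class{GPMap}.
#' @return An object of the requested G-P map class.
#' @examples
#' gp <- additiveGPMap(2, builtinAlphabet("dna"),
#'                     theta0 = 0.5,
#'                     thetaLC = rbind(c(1, 0, 0, 0), c(0, 0, 0, -2)))
#' phi(gp, "AT")
#' @export
additiveGPMap <- function(L, alphabet, theta0 = 0, thetaLC = NULL) {
  C <- alphabetSize(alphabet)
  if (is.null(thetaLC)) thetaLC <- matrix(0, L, C)
  new("AdditiveGPMap", L = as.integer(L), nchars = as.integer(C),
      alphabet = alphabet, theta0 = as.numeric(theta0),
      thetaLC = as.matrix(thetaLC))
}

#' @rdname additiveGPMap
#' @export
neighborGPMap <- function(L, alphabet, theta0 = 0, thetaLC = NULL,
                          thetaPairs = NULL) {
  C <- alphabetSize(alphabet)
  pairs <- .position_pairs(L, neighborOnly = TRUE)
  if (is.null(thetaLC)) thetaLC <- matrix(0, L, C)
  if (is.null(thetaPairs)) thetaPairs <- numeric(nrow(pairs) * C * C)
  new("NeighborGPMap", L = as.integer(L), nchars = as.integer(C),
      alphabet = alphabet, theta0 = as.numeric(theta0),
      thetaLC = as.matrix(thetaLC), thetaPairs = as.numeric(thetaPairs),
      pairs = pairs)
}

#' @rdname additiveGPMap
#' @export
pairwiseGPMap <- function(L, alphabet, theta0 = 0, thetaLC = NULL,
                          thetaPairs = NULL) {
  C <- alphabetSize(alphabet)
  pairs <- .position_pairs(L, neighborOnly = FALSE)
  if (is.null(thetaLC)) thetaLC <- matrix(0, L, C)
  if (is.null(thetaPairs)) thetaPairs <- numeric(nrow(pairs) * C * C)
  new("PairwiseGPMap", L = as.integer(L), nchars = as.integer(C),
      alphabet = alphabet, theta0 = as.numeric(theta0),
      thetaLC = as.matrix(thetaLC), thetaPairs = as.numeric(thetaPairs),
      pairs = pairs)
}

#' Latent phenotype of sequences under a G-P map
#'
#' @param map a \linkS4class{GPMap}.
#' @param sequences character vector of sequences (length L, over the
#'   map's alphabet).
#' @return Numeric vector of latent phenotypes; \code{NA} (with a warning)
#'   for sequences using a (position, character) whose additive effect is
#'   undefined.
#' @export
setGeneric("phi", function(map, sequences) standardGeneric("phi"))

#' @rdname phi
#' @export
setMethod("phi", "AdditiveGPMap", function(map, sequences) {
  idx <- .seq_to_idx(sequences, map@alphabet)
  .check_L(map, idx)
  out <- map@theta0 + .additive_part(map, idx)
  if (is(map, "NeighborGPMap")) out <- out + .pair_part(map, idx)
  if (anyNA(out))
    warning(sum(is.na(out)), " sequence(s) use effects with undefined ",
            "(NA) parameters; phi returned as NA")
  out
})

.check_L <- function(map, idx) {
  if (ncol(idx) != map@L)
    stop("sequence length ", ncol(idx), " does not match map L = ", map@L)
}

.additive_part <- function(map, idx) {
  L <- map@L
  v <- numeric(nrow(idx))
  for (l in seq_len(L)) v <- v + map@thetaLC[cbind(l, idx[, l])]
  v
}

.pair_part <- function(map, idx) {
  C <- map@nchars
  v <- numeric(nrow(idx))
  pairs <- map@pairs
  for (p in seq_len(nrow(pairs))) {
    l <- pairs[p, 1] + 1L; lp <- pairs[p, 2] + 1L
    j <- (p - 1L) * C * C + (idx[, l] - 1L) * C + idx[, lp]
    v <- v + map@thetaPairs[j]
  }
  v
}

#' Number of trainable parameters of a G-P map
#'
#' @param map a \linkS4class{GPMap}.
#' @return Integer count: additive maps have \eqn{1 + LC}; neighbor maps
#'   add \eqn{(L-1)C^2}; pairwise maps add \eqn{L(L-1)C^2/2}.
#' @export
setGeneric("nParams", function(map) standardGeneric("nParams"))

#' @rdname nParams
#' @export
setMethod("nParams", "AdditiveGPMap", function(map) {
  n <- 1L + map@L * map@nchars
  if (is(map, "NeighborGPMap")) n <- n + length(map@thetaPairs)
  n
})

setMethod("show", "AdditiveGPMap", function(object) {
  kind <- if (is(object, "PairwiseGPMap")) "pairwise"
          else if (is(object, "NeighborGPMap")) "neighbor" else "additive"
  cat(kind, "G-P map: L =", object@L, ", C =", object@nchars,
      "(", object@alphabet@name, "),", nParams(object), "parameters\n")
})

#' Export G-P map parameters as a tidy table
#'
#' Returns a long-format data.frame suitable for sequence-logo tools:
#' additive effects with columns \code{l}, \code{c}, \code{value} and
#' interaction effects with columns \code{l}, \code{c}, \code{lp},
#' \code{cp}, \code{value}; positions are 0-based.
#'
#' @param map a parametric \linkS4class{GPMap}.
#' @return A list with elements \code{theta0}, \code{additive}, and (when
#'   present) \code{pairwise}.
#' @export
exportParams <- function(map) {
  stopifnot(is(map, "AdditiveGPMap"))
  chars <- map@alphabet@characters
  add <- data.frame(
    l = rep(0:(map@L - 1L), each = map@nchars),
    c = rep(chars, map@L),
    value = as.vector(t(map@thetaLC)))
  out <- list(theta0 = map@theta0, additive = add)
  if (is(map, "NeighborGPMap") && length(map@thetaPairs)) {
    C <- map@nchars; pr <- map@pairs
    out$pairwise <- data.frame(
      l = rep(pr[, 1], each = C * C),
      c = rep(rep(chars, each = C), nrow(pr)),
      lp = rep(pr[, 2], each = C * C),
      cp = rep(chars, C * nrow(pr)),
      value = map@thetaPairs)
  }
  out
}

# ---- internal: flat parameter vector <-> map object ----------------------
# layout: theta0, thetaLC row-major (matching oneHotEncode columns),
# thetaPairs (matching pairwiseFeatures columns)
.gp_pack <- function(map) {
  v <- c(map@theta0, as.vector(t(map@thetaLC)))
  if (is(map, "NeighborGPMap")) v <- c(v, map@thetaPairs)
  v
}

.gp_unpack <- function(map, v) {
  LC <- map@L * map@nchars
  map@theta0 <- v[1]
  map@thetaLC <- matrix(v[2:(1 + LC)], map@L, map@nchars, byrow = TRUE)
  if (is(map, "NeighborGPMap"))
    map@thetaPairs <- v[(2 + LC):length(v)]
  map
}
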