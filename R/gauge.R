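#' Position probability matrix for gauge fixing
#'
#' The hierarchical gauge is defined relative to a factorized probability
#' distribution over sequence space, represented as an L x C matrix
#' \eqn{p_{l:c}} whose rows sum to 1. Three built-in choices: uniform
#' (\eqn{1/C}), empirical (\eqn{n_{l:c}/N} character frequencies of a
#' dataset), and wildtype (the one-hot encoding of a reference sequence).
#'
#' @param L sequence length.
#' @param alphabet an \linkS4class{Alphabet}.
#' @param source one of "uniform", "empirical", "wildtype".
#' @param sequences character vector of sequences (required for
#'   "empirical").
#' @param wildtype a single reference sequence (required for "wildtype").
#' @return An L x C probability matrix with attribute \code{source}.
#' @export
gaugeDistribution <- function(L, alphabet,
                              source = c("uniform", "empirical", "wildtype"),
                              sequences = NULL, wildtype = NULL) {
  source <- match.arg(source)
  C <- alphabetSize(alphabet)
  p <- switch(source,
    uniform = matrix(1 / C, L, C),
    empirical = {
      if (is.null(sequences)) stop("empirical gauge needs 'sequences'")
      idx <- .seq_to_idx(sequences, alphabet)
      t(apply(idx, 2, function(col) tabulate(col, C) / length(col)))
    },
    wildtype = {
      if (is.null(wildtype)) stop("wildtype gauge needs 'wildtype'")
      idx <- .seq_to_idx(wildtype, alphabet)
      m <- matrix(0, L, C)
      m[cbind(seq_len(L), idx[1, ])] <- 1
      m
    })
  attr(p, "source") <- source
  p
}

#' Hierarchical gauge fixing of parametric G-P maps
#'
#' Adjusts gauge degrees of freedom — parameter directions that leave
#' \eqn{\phi(x)} unchanged for every sequence — so that lower-order terms
#' account for the highest possible fraction of variance in \eqn{\phi}
#' under a factorized sequence distribution \eqn{p_{l:c}}. After fixing,
#' additive effects average to zero at each position under \eqn{p},
#' interaction blocks have zero \eqn{p}-weighted marginals in both indices,
#' and the transformation is idempotent. \eqn{\phi} is preserved exactly.
#'
#' @param map an additive, neighbor or pairwise \linkS4class{GPMap}
#'   (custom maps are never gauge-fixed automatically).
#' @param p an L x C probability matrix from
#'   \code{\link{gaugeDistribution}}; defaults to the uniform gauge.
#' @return The gauge-fixed map (same class as the input).
#' @examples
#' gp <- additiveGPMap(1, Alphabet("AB"), theta0 = 0,
#'                     thetaLC = matrix(c(2, 4), 1))
#' hierarchicalGauge(gp)  # theta0 = 3, effects (-1, 1)
#' @export
hierarchicalGauge <- function(map, p = NULL) {
  stopifnot(is(map, "AdditiveGPMap"))
  L <- map@L; C <- map@nchars
  if (is.null(p)) p <- gaugeDistribution(L, map@alphabet, "uniform")
  stopifnot(nrow(p) == L, ncol(p) == C)
  th <- map@thetaLC
  if (any(is.na(th) & p > 0))
    stop("NA additive parameters at positions with p > 0; ",
         "cannot gauge-fix (use a wildtype gauge avoiding them)")
  th0 <- map@theta0
  pairAdj <- matrix(0, L, C)  # interaction terms folded into additive
  if (is(map, "NeighborGPMap") && length(map@thetaPairs)) {
    pr <- map@pairs
    newPairs <- map@thetaPairs
    for (k in seq_len(nrow(pr))) {
      l <- pr[k, 1] + 1L; lp <- pr[k, 2] + 1L
      M <- matrix(map@thetaPairs[((k - 1L) * C * C + 1L):(k * C * C)],
                  C, C, byrow = TRUE)  # rows c (position l), cols c' (lp)
      p1 <- p[l, ]; p2 <- p[lp, ]
      rowm <- as.vector(M %*% p2)       # sum_c' M[c, c'] p2[c']
      colm <- as.vector(p1 %*% M)       # sum_c M[c, c'] p1[c]
      mm <- as.numeric(p1 %*% M %*% p2)
      th0 <- th0 + mm
      pairAdj[l, ]  <- pairAdj[l, ]  + (rowm - mm)
      pairAdj[lp, ] <- pairAdj[lp, ] + (colm - mm)
      Mfix <- M - outer(rep(1, C), colm) - outer(rowm, rep(1, C)) + mm
      newPairs[((k - 1L) * C * C + 1L):(k * C * C)] <- as.vector(t(Mfix))
    }
    map@thetaPairs <- newPairs
  }
  tp <- th * p
  tp[p == 0] <- 0                       # NA effects allowed where p = 0
  rowMeansP <- rowSums(tp)              # sum_c theta_lc p_lc per position
  th0 <- th0 + sum(rowMeansP)
  map@thetaLC <- th - rowMeansP + pairAdj
  map@theta0 <- th0
  map
}

#' Diffeomorphic (affine) mode fixing
#'
#' Centers and scales the latent phenotype so that training-set \eqn{\phi}
#' values have mean 0 and standard deviation 1, compensating inside the
#' measurement process so every prediction \eqn{p(y|x)} is unchanged:
#' \eqn{\theta_0 \to \theta_0 - a}, \eqn{\theta \to \theta / b}, and for GE
#' regression \eqn{g(\phi) \to g(a + b\phi)} (for MPA regression
#' \eqn{p(y|\phi) \to p(y|a + b\phi)}).
#'
#' @param model a \linkS4class{LatentModel}.
#' @param trainingPhi latent phenotype values on the training data (used
#'   for the centering constants; must have positive variance).
#' @return The model with standardized latent phenotype; the constants are
#'   recorded in \code{model@diffeo}.
#' @export
fixDiffeomorphic <- function(model, trainingPhi) {
  a <- mean(trainingPhi); b <- stats::sd(trainingPhi)
  if (!is.finite(b) || b <= 0)
    stop("training phi has zero variance; degenerate G-P map")
  gp <- model@gpmap
  if (is(gp, "AdditiveGPMap")) {
    gp@theta0 <- (gp@theta0 - a) / b
    gp@thetaLC <- gp@thetaLC / b
    if (is(gp, "NeighborGPMap")) gp@thetaPairs <- gp@thetaPairs / b
  } else if (is(gp, "BlackBoxGPMap")) {
    nl <- length(gp@weights)
    gp@weights[[nl]]$W <- gp@weights[[nl]]$W / b
    gp@weights[[nl]]$b <- (gp@weights[[nl]]$b - a) / b
  } else {
    stop("diffeomorphic fixing is not applied to custom G-P maps")
  }
  model@gpmap <- gp
  meas <- model@measurement
  if (is(meas, "GEMeasurement")) {
    if (meas@nonlin@kind == "linear") {
      meas@nonlin@a <- meas@nonlin@a + meas@nonlin@b[1] * a
      meas@nonlin@b <- meas@nonlin@b * b
    } else {
      meas@nonlin@d <- meas@nonlin@d + meas@nonlin@c * a
      meas@nonlin@c <- meas@nonlin@c * b
    }
  } else {
    meas@d <- meas@d + meas@c * a
    meas@c <- meas@c * b
  }
  model@measurement <- meas
  model@diffeo <- c(a = a, b = b)
  model
}
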