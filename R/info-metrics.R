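.ln2 <- log(2)

# deterministic tie-breaking jitter: kNN estimators need distinct distances
.jitter <- function(x, scale = 1e-10) {
  if (anyDuplicated(x)) {
    rg <- diff(range(x))
    if (rg == 0) rg <- 1
    x <- x + stats::runif(length(x), -1, 1) * scale * rg
  }
  x
}

#' k-nearest-neighbor entropy estimator
#'
#' Kozachenko-Leonenko estimate of the differential entropy of continuous
#' samples, in bits, using Chebyshev (max-norm) distances:
#' \eqn{H = \psi(N) - \psi(k) + d\log_2 2 + (d/N)\sum_i \log_2 \epsilon_i}
#' with \eqn{\epsilon_i} the distance to the k-th nearest neighbour.
#' Duplicate values are broken by adding uniform jitter of 1e-10 times the
#' data range (drawn from the current RNG stream).
#'
#' @param x numeric vector (1-D samples) or matrix (rows = samples).
#' @param k neighbour count, \code{1 <= k < n} (default 5).
#' @return Entropy estimate in bits.
#' @examples
#' set.seed(1)
#' knnEntropy(runif(2000))  # about 0
#' @export
knnEntropy <- function(x, k = 5L) {
  X <- as.matrix(x)
  n <- nrow(X); d <- ncol(X)
  if (n <= k) stop("need n > k samples")
  for (j in seq_len(d)) X[, j] <- .jitter(X[, j])
  eps <- cpp_knn_dist(X, as.integer(k))
  (digamma(n) - digamma(k) + d * .ln2 + d * mean(log(eps))) / .ln2
}

#' KSG mutual information estimator
#'
#' Kraskov-Stogbauer-Grassberger (algorithm 1) estimate of the mutual
#' information between two paired continuous samples, in bits. Neighbour
#' balls use the Chebyshev norm in the joint space; marginal neighbour
#' counts use a strict radius. Small negative estimates are floored at 0
#' (the raw value is kept in the \code{"raw"} attribute); constant inputs
#' return 0 with a warning. The local-nonuniformity correction of Gao et
#' al. is exposed as an optional hook but not implemented.
#'
#' @param x,y paired numeric vectors.
#' @param k neighbour count (default 5).
#' @param gaoCorrection must be \code{FALSE}; reserved.
#' @return Mutual information estimate in bits (>= 0).
#' @examples
#' set.seed(1)
#' ksgMutualInformation(rnorm(500), rnorm(500))  # about 0
#' @export
ksgMutualInformation <- function(x, y, k = 5L, gaoCorrection = FALSE) {
  if (gaoCorrection)
    stop("the local-nonuniformity correction is not implemented")
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= k) stop("need n > k samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; mutual information estimated as 0")
    return(structure(0, raw = 0))
  }
  x <- .jitter(x); y <- .jitter(y)
  eps <- cpp_knn_dist(cbind(x, y), as.integer(k))
  nx <- cpp_count_within(x, eps)
  ny <- cpp_count_within(y, eps)
  I <- (digamma(k) + digamma(n) -
        mean(digamma(nx + 1) + digamma(ny + 1))) / .ln2
  structure(max(I, 0), raw = I)
}

#' Half-sample subsampling uncertainty for an estimator
#'
#' Standard error of an entropy or mutual-information estimate obtained
#' from R random half-samples of the data:
#' \eqn{\delta E = \mathrm{std}(\{E_r\}) / \sqrt{2}} (half-sampling is
#' preferred over bootstrap resampling, which biases kNN entropies).
#'
#' @param estimator function taking a row subset of \code{data}.
#' @param data vector, matrix or data.frame of observations (rows).
#' @param R number of half-samples (default 25).
#' @return Estimated standard error \eqn{\delta E}.
#' @export
subsampleUncertainty <- function(estimator, data, R = 25L) {
  stopifnot(R >= 2L)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 4L) stop("too few observations to halve")
  half <- floor(n / 2)
  est <- vapply(seq_len(R), function(r) {
    idx <- sample.int(n, half)
    sub <- if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
    as.numeric(estimator(sub))
  }, 0)
  stats::sd(est) / sqrt(2)
}

# discrete plug-in entropy (bits)
.discrete_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  -sum(p * log2(p))
}

# entropy decomposition I[y; phi] for discrete y, continuous phi
.discrete_mi <- function(bins, phiVals, k) {
  H <- knnEntropy(phiVals, k)
  for (b in unique(bins)) {
    sel <- bins == b
    nb <- sum(sel)
    if (nb >= 3L)
      H <- H - (nb / length(bins)) *
        knnEntropy(phiVals[sel], min(k, nb - 1L))
  }
  max(H, 0)
}

#' Predictive information of a G-P map
#'
#' \eqn{I_{pre} = I[y; \phi]} estimated on data not used for training: the
#' mutual information between measurements and the latent phenotypes the
#' map assigns. Continuous y uses the KSG estimator; discrete y uses the
#' decomposition \eqn{I[y;\phi] = H[\phi] - \sum_y p(y) H_y[\phi]} with
#' per-bin kNN entropies. Does not depend on the measurement-process
#' parameters.
#'
#' @param model a \linkS4class{LatentModel} (or \linkS4class{GPMap}).
#' @param testData held-out \linkS4class{MaveDataset}.
#' @param k neighbour count.
#' @param R half-samples for the uncertainty (0 to skip).
#' @return List with \code{I} (bits) and \code{dI} (standard error; NA if
#'   skipped).
#' @export
predictiveInformation <- function(model, testData, k = 5L, R = 25L) {
  if (nObs(testData) <= k + 1L) stop("test set too small for k = ", k)
  gpm <- if (is(model, "LatentModel")) model@gpmap else model
  mode <- datasetMode(testData)
  if (mode == "mpa_counts") testData <- countsToBins(testData)
  phiVals <- phi(gpm, testData@sequences)
  if (anyNA(phiVals)) stop("phi undefined for some test sequences")
  if (datasetMode(testData) == "ge") {
    y <- testData@y
    est <- function(d) ksgMutualInformation(d[, 1], d[, 2], k)
    dat <- cbind(y, phiVals)
  } else {
    y <- testData@bins
    est <- function(d) .discrete_mi(d[, 1], d[, 2], k)
    dat <- cbind(y, phiVals)
  }
  I <- as.numeric(est(dat))
  dI <- if (R >= 2L) subsampleUncertainty(est, dat, R) else NA_real_
  list(I = I, dI = dI)
}

#' Variational information of a full latent model
#'
#' \eqn{I_{var} = H[y] - (\log_2 e / N) L_{like}}, a linear transformation
#' of log likelihood that lower-bounds \eqn{I_{pre}}. The uncertainty is
#' \eqn{\delta I_{var} = \sqrt{\delta H[y]^2 + var(\{Q_n\})/N}} with
#' \eqn{Q_n = -\log_2 p(y_n|\phi_n)}.
#'
#' @param model a \linkS4class{LatentModel}.
#' @param testData held-out \linkS4class{MaveDataset}.
#' @param k neighbour count for the entropy of continuous y.
#' @param R half-samples for \eqn{\delta H[y]} (0 to skip).
#' @return List with \code{I}, \code{dI}, \code{Hy}, \code{dHy} (bits).
#' @export
variationalInformation <- function(model, testData, k = 5L, R = 25L) {
  mode <- datasetMode(testData)
  if (mode == "mpa_counts") testData <- countsToBins(testData)
  N <- nObs(testData)
  phiVals <- phi(model@gpmap, testData@sequences)
  if (is(model@measurement, "GEMeasurement")) {
    yhat <- evalNonlinearity(model@measurement@nonlin, phiVals)
    ll <- noiseLogPdf(model@measurement@noise, testData@y, yhat,
                      se = testData@se)
    Hy <- knnEntropy(testData@y, k)
    dHy <- if (R >= 2L)
      subsampleUncertainty(function(d) knnEntropy(d, k), testData@y, R)
      else 0
  } else {
    P <- mpaProbabilities(model@measurement, phiVals)
    ll <- log(P[cbind(seq_len(N), testData@bins + 1L)])
    Hy <- .discrete_entropy(testData@bins)
    dHy <- if (R >= 2L)
      subsampleUncertainty(.discrete_entropy, testData@bins, R)
      else 0
  }
  ll[!is.finite(ll) | ll < -690] <- -690
  Q <- -ll / .ln2
  list(I = Hy - mean(Q), dI = sqrt(dHy^2 + stats::var(Q) / N),
       Hy = Hy, dHy = dHy)
}

#' Upper bound on intrinsic information from read-count noise
#'
#' For log-enrichment data derived from input/output read counts, Poisson
#' counting noise implies a per-variant measurement uncertainty
#' \eqn{\delta y_n = \log_2(e)\sqrt{1/(c^{in}_n+1) + 1/(c^{out}_n+1)}};
#' assuming \eqn{p(y|x)} Gaussian, the conditional entropy is
#' \eqn{H_x[y] = \frac{1}{2}\log_2(2\pi e\,\delta y_n^2)} and
#' \eqn{I[x;y] \le H[y] - \langle H_x[y]\rangle}. The bound diverges as
#' counts grow (conditional entropy \eqn{\to -\infty}) and is unreliable
#' for over-dispersed counts — treat it as an upper reference, not an
#' estimate.
#'
#' @param y measurements (log2 enrichment scale).
#' @param cIn,cOut per-variant input/output read counts.
#' @param k neighbour count for \eqn{H[y]}.
#' @param R half-samples for \eqn{\delta H[y]}.
#' @return List with \code{bound}, \code{dBound}, \code{Hy},
#'   \code{meanHxy} (bits).
#' @export
intrinsicInfoUpper <- function(y, cIn, cOut, k = 5L, R = 25L) {
  if (missing(cIn) || missing(cOut) || is.null(cIn) || is.null(cOut))
    stop("per-variant input/output read counts are required")
  dy <- log2(exp(1)) * sqrt(1 / (cIn + 1) + 1 / (cOut + 1))
  Hxy <- 0.5 * log2(2 * pi * exp(1) * dy^2)
  Hy <- knnEntropy(y, k)
  dHy <- if (R >= 2L)
    subsampleUncertainty(function(d) knnEntropy(d, k), y, R) else 0
  dMean <- stats::sd(Hxy) / sqrt(length(Hxy))
  list(bound = Hy - mean(Hxy), dBound = sqrt(dHy^2 + dMean^2),
       Hy = Hy, meanHxy = mean(Hxy))
}

#' Lower bound on intrinsic information
#'
#' The Markov chain \eqn{y \leftarrow x \rightarrow y'} gives
#' \eqn{I[x;y] \ge I[y;y']} for replicate measurements, and the data
#' processing inequality gives \eqn{I[x;y] \ge I_{pre}} for any model's
#' predictive information on test data. The larger available bound is
#' returned. A replicate identical to \eqn{y} degenerates to the
#' (jittered) self-information of a continuous variable, which is limited
#' by the estimator rather than the data.
#'
#' @param y measurements.
#' @param yReplicate replicate measurements paired by sequence (optional).
#' @param modelIpre a model's predictive information with uncertainty, as
#'   returned by \code{\link{predictiveInformation}} (optional).
#' @param k,R estimator settings.
#' @return List with \code{bound}, \code{dBound}, \code{source}.
#' @export
intrinsicInfoLower <- function(y, yReplicate = NULL, modelIpre = NULL,
                               k = 5L, R = 25L) {
  cand <- list()
  if (!is.null(yReplicate)) {
    est <- function(d) ksgMutualInformation(d[, 1], d[, 2], k)
    dat <- cbind(y, yReplicate)
    cand$replicate <- list(bound = as.numeric(est(dat)),
      dBound = if (R >= 2L) subsampleUncertainty(est, dat, R) else NA_real_)
  }
  if (!is.null(modelIpre))
    cand$model <- list(bound = modelIpre$I, dBound = modelIpre$dI)
  if (!length(cand))
    stop("need replicate measurements or a model's predictive information")
  best <- which.max(vapply(cand, function(x) x$bound, 0))
  c(cand[[best]], list(source = names(cand)[best]))
}

#' Information report for a fitted model
#'
#' Convenience wrapper computing the information metrics on held-out
#' data: variational and predictive information with uncertainties, and
#' the measurement entropy.
#'
#' @param model a \linkS4class{LatentModel}.
#' @param testData held-out \linkS4class{MaveDataset}.
#' @param k neighbour count; @param R half-samples.
#' @return data.frame with columns metric, bits, se.
#' @export
informationReport <- function(model, testData, k = 5L, R = 25L) {
  iv <- variationalInformation(model, testData, k, R)
  ip <- predictiveInformation(model, testData, k, R)
  data.frame(metric = c("I_var", "I_pre", "H_y"),
             bits = c(iv$I, ip$I, iv$Hy),
             se = c(iv$dI, ip$dI, iv$dHy))
}
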