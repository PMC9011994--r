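.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-9))))
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Split observations into train/validation/test sets
#'
#' Random (seeded) shuffle split with the given positive fractions
#' (summing to 1); default 90:5:5.
#'
#' @param n number of observations.
#' @param fractions length-3 positive vector of train, validation, test
#'   fractions.
#' @param seed RNG seed.
#' @return List with integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
splitIndices <- function(n, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  ord <- sample.int(n)
  nTr <- max(1L, round(fractions[1] * n))
  nVa <- max(1L, round(fractions[2] * n))
  nTr <- min(nTr, n - 2L)
  list(train = sort(ord[seq_len(nTr)]),
       val = sort(ord[(nTr + 1L):(nTr + nVa)]),
       test = sort(ord[(nTr + nVa + 1L):n]))
}

#' Enforce dataset-driven model constraints
#'
#' When every non-reference sequence in the library differs from the
#' reference (the most frequent sequence, or a user-specified one) by at
#' most one position, the shape of the measurement nonlinearity is
#' unidentifiable: the effects of single mutations are confounded with
#' any monotone transformation. For such libraries only an additive G-P
#' map with GE regression and a linear nonlinearity is permitted
#' (heteroscedastic noise is still allowed). Multiple-mutation variants
#' lift the restriction.
#'
#' @param dataset a \linkS4class{MaveDataset}.
#' @param gpmapKind "additive", "neighbor", "pairwise", "blackbox" or
#'   "custom".
#' @param process "ge" or "mpa".
#' @param linearNonlin whether the GE nonlinearity is constrained linear.
#' @param reference optional reference sequence (defaults to the most
#'   frequent sequence in the dataset).
#' @return Invisibly, a list with \code{singleMutantOnly} and
#'   \code{reference}; errors if the requested specification is not
#'   permitted for the dataset.
#' @export
enforceLibraryConstraints <- function(dataset, gpmapKind, process,
                                      linearNonlin = FALSE,
                                      reference = NULL) {
  seqs <- dataset@sequences
  if (is.null(reference)) {
    tab <- table(factor(seqs, levels = unique(seqs)))  # ties: first seen
    reference <- names(tab)[which.max(tab)]
  }
  idx <- .seq_to_idx(seqs, dataset@alphabet)
  ref <- .seq_to_idx(reference, dataset@alphabet)[1, ]
  hd <- rowSums(idx != matrix(ref, nrow(idx), length(ref), byrow = TRUE))
  singleOnly <- all(hd <= 1L)
  if (singleOnly &&
      !(gpmapKind == "additive" && process == "ge" && linearNonlin))
    stop("the library contains only single-mutation variants of '",
         reference, "'; experimental nonlinearities are unidentifiable ",
         "from such data, so only an additive G-P map with GE regression ",
         "and a linear nonlinearity (linearNonlin = TRUE) is permitted. ",
         "Include multiple-mutation variants to lift this restriction.")
  invisible(list(singleMutantOnly = singleOnly, reference = reference))
}

# ---- internal: numeric d log p / d yhat (vectorized over data) ----------
.dlp_dyhat <- function(noise, y, yhat, se, h) {
  (noiseLogPdf(noise, y, yhat + h, se) -
   noiseLogPdf(noise, y, yhat - h, se)) / (2 * h)
}

.make_noise <- function(family, nc, polyOrder) {
  Kp <- polyOrder + 1L
  switch(family,
    gaussian = gaussianNoise(nc),
    cauchy = cauchyNoise(nc),
    skewt = skewTNoise(nc[seq_len(Kp)], nc[Kp + seq_len(Kp)],
                       nc[2L * Kp + seq_len(Kp)]),
    empirical = empiricalNoise())
}

#' Fit a latent phenotype model by regularized maximum likelihood
#'
#' Jointly infers the G-P map and the measurement process by minimizing
#' the negative log likelihood plus an L2 penalty
#' (\eqn{\lambda_\theta\|\theta\|^2 + \lambda_\eta\|\eta\|^2}) with
#' minibatch Adam and early stopping on validation loss. G-P map
#' parameters initialize from a seeded ridge regression of the (suitably
#' summarized) measurements on sequence features; the nonlinearity
#' initializes from a least-squares fit of tanh basis functions spread
#' over the initial latent range. After training, diffeomorphic modes are
#' fixed (training \eqn{\phi} standardized to mean 0, sd 1) and, for
#' parametric maps, the hierarchical gauge is applied; additive effects of
#' (position, character) combinations never observed in training are set
#' to \code{NA}. The fit is deterministic given \code{seed}.
#'
#' @param dataset a \linkS4class{MaveDataset}; its mode selects GE
#'   (continuous y) or MPA (bins/counts) regression.
#' @param gpmap "additive", "neighbor", "pairwise", "blackbox", or a
#'   ready-made \linkS4class{GPMap} (e.g. a \linkS4class{CustomGPMap}).
#' @param noise GE noise family: "gaussian", "cauchy", "skewt" or
#'   "empirical" (requires per-measurement standard errors).
#' @param K hidden tanh nodes of the GE nonlinearity (default 20).
#' @param mpaK hidden nodes per bin of the MPA process (default 10).
#' @param polyOrder order of the exponentiated polynomials parameterizing
#'   the noise model (default 2; 0 is homoscedastic).
#' @param lambdaTheta,lambdaEta L2 penalty weights (defaults 1e-3, 1e-1).
#' @param split train/validation/test fractions (default 90:5:5).
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size (custom maps train full-batch).
#' @param learnRate Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed controlling split, initialization and shuffling.
#' @param gauge gauge distribution for hierarchical gauge fixing.
#' @param wildtype reference sequence for the wildtype gauge.
#' @param monotonic constrain the GE nonlinearity to be non-decreasing.
#' @param linearNonlin constrain the GE nonlinearity to be linear
#'   (required for single-mutant-only libraries).
#' @param reference optional reference sequence for the single-mutant
#'   check.
#' @param hidden hidden-layer sizes for the black-box map.
#' @param verbose print progress every 25 epochs.
#' @return A gauge-fixed \linkS4class{LatentModel} with training
#'   \code{history} (epoch, loss, valLoss, Ivar in bits) and the data
#'   \code{split}.
#' @export
fitLatentModel <- function(dataset, gpmap = "additive",
    noise = c("skewt", "gaussian", "cauchy", "empirical"),
    K = 20L, mpaK = 10L, polyOrder = 2L,
    lambdaTheta = 1e-3, lambdaEta = 1e-1,
    split = c(0.9, 0.05, 0.05), epochs = 300L, batchSize = 100L,
    learnRate = 1e-3, patience = 30L, seed = 1L,
    gauge = c("uniform", "empirical", "wildtype"), wildtype = NULL,
    monotonic = TRUE, linearNonlin = FALSE, reference = NULL,
    hidden = c(10L, 10L), verbose = FALSE) {
  noise <- match.arg(noise)
  gauge <- match.arg(gauge)
  mode <- datasetMode(dataset)
  process <- if (mode == "ge") "ge" else "mpa"
  alph <- dataset@alphabet
  L <- nchar(dataset@sequences[1])
  if (noise == "empirical" && process == "ge" && !length(dataset@se))
    stop("empirical noise requires per-measurement standard errors (se)")

  # resolve the G-P map
  if (is.character(gpmap)) {
    gpKind <- match.arg(gpmap,
      c("additive", "neighbor", "pairwise", "blackbox"))
    gp <- switch(gpKind,
      additive = additiveGPMap(L, alph),
      neighbor = neighborGPMap(L, alph),
      pairwise = pairwiseGPMap(L, alph),
      blackbox = blackboxGPMap(L, alph, hidden = hidden, seed = seed))
  } else {
    gp <- gpmap
    gpKind <- if (is(gp, "PairwiseGPMap")) "pairwise"
      else if (is(gp, "NeighborGPMap")) "neighbor"
      else if (is(gp, "AdditiveGPMap")) "additive"
      else if (is(gp, "BlackBoxGPMap")) "blackbox"
      else "custom"
  }
  enforceLibraryConstraints(dataset, gpKind, process, linearNonlin,
                            reference)

  set.seed(seed)
  sp <- splitIndices(nObs(dataset), split, seed = seed)
  seqs <- dataset@sequences
  trainRows <- sp$train; valRows <- sp$val

  # ---- design / feature construction ------------------------------------
  linearGP <- gpKind %in% c("additive", "neighbor", "pairwise")
  isCustom <- gpKind == "custom"
  if (linearGP) {
    X1 <- oneHotEncode(seqs, alph)
    D <- cbind(1, X1)
    if (gpKind != "additive")
      D <- cbind(D, pairwiseFeatures(X1, neighborOnly = gpKind == "neighbor"))
    Dtr <- D[trainRows, , drop = FALSE]
    Dva <- D[valRows, , drop = FALSE]
    pTheta <- ncol(D)
  } else if (gpKind == "blackbox") {
    Fall <- .bb_features(gp, seqs)
    Dtr <- Fall[trainRows, , drop = FALSE]
    Dva <- Fall[valRows, , drop = FALSE]
    pTheta <- nParams(gp)
  } else {
    prepTr <- gp@prepare(seqs[trainRows], alph)
    prepVa <- gp@prepare(seqs[valRows], alph)
    pTheta <- length(gp@params)
    batchSize <- length(trainRows)  # full batch for custom maps
  }
  nTr <- length(trainRows)

  # observation weights / targets
  if (process == "ge") {
    ytr <- dataset@y[trainRows]; yva <- dataset@y[valRows]
    setr <- if (length(dataset@se)) dataset@se[trainRows] else NULL
    seva <- if (length(dataset@se)) dataset@se[valRows] else NULL
    nObsTr <- nTr
    scY <- max(stats::sd(ytr), 1e-3)
  } else {
    Cmat <- switch(mode,
      mpa_bins = {
        Y <- max(dataset@bins) + 1L
        m <- matrix(0, nObs(dataset), Y)
        m[cbind(seq_len(nObs(dataset)), dataset@bins + 1L)] <- 1
        m
      },
      mpa_counts = dataset@counts)
    Y <- ncol(Cmat)
    Ctr <- Cmat[trainRows, , drop = FALSE]
    Cva <- Cmat[valRows, , drop = FALSE]
    Ntr <- rowSums(Ctr); Nva <- rowSums(Cva)
    nObsTr <- sum(Ctr)
  }

  # ---- parameter initialization -----------------------------------------
  zTarget <- if (process == "ge") ytr else as.vector((Ctr %*%
    (0:(Y - 1L))) / pmax(Ntr, 1))
  z <- (zTarget - mean(zTarget)) / max(stats::sd(zTarget), 1e-8)
  if (linearGP) {
    ridge <- crossprod(Dtr) + diag(1, pTheta)
    theta0 <- as.vector(solve(ridge, crossprod(Dtr, z)))
    phi0 <- as.vector(Dtr %*% theta0)
    sd0 <- max(stats::sd(phi0), 1e-8)
    theta0 <- theta0 / sd0
    phi0 <- phi0 / sd0
  } else if (gpKind == "blackbox") {
    theta0 <- .mlp_pack(gp@weights)
    phi0 <- .mlp_forward(gp@weights, Dtr, gp@activation)$phi
    sd0 <- max(stats::sd(phi0), 1e-6)
    w <- gp@weights; nl <- length(w)
    w[[nl]]$W <- w[[nl]]$W / sd0
    w[[nl]]$b <- (w[[nl]]$b - mean(phi0)) / sd0
    gp@weights <- w
    theta0 <- .mlp_pack(w)
    phi0 <- (phi0 - mean(phi0)) / sd0
  } else {
    theta0 <- unname(gp@params)
    phi0 <- gp@phiFun(gp@params, prepTr)
    if (!all(is.finite(phi0)))
      stop("custom G-P map produced non-finite phi on training data")
  }

  if (process == "ge") {
    if (linearNonlin) {
      slope0 <- stats::cov(phi0, ytr) / max(stats::var(phi0), 1e-8)
      alpha0 <- c(mean(ytr) - slope0 * mean(phi0), slope0)
      nAlpha <- 2L
    } else {
      # monotone init: isotonic regression of y on phi0, then tanh nodes
      # spread over the phi range with amplitudes from the curve increments
      grid <- seq(stats::quantile(phi0, 0.02), stats::quantile(phi0, 0.98),
                  length.out = K)
      o <- order(phi0)
      iso <- stats::isoreg(phi0[o], ytr[o])
      gfun <- stats::approxfun(phi0[o], iso$yf, rule = 2, ties = mean)
      # increments of the isotonic curve between node midpoints
      edges <- c(min(phi0), (grid[-1] + grid[-K]) / 2, max(phi0))
      inc <- pmax(diff(gfun(edges)), 0)
      bInit <- pmax(inc / 2, 1e-3 * scY)
      aInit <- mean(ytr) - sum(bInit * tanh(mean(phi0) - grid))
      alpha0 <- c(aInit,
                  if (monotonic) .softplus_inv(bInit) else bInit,
                  rep(if (monotonic) .softplus_inv(1) else 1, K),
                  -grid)
      nAlpha <- 1L + 3L * K
    }
    Kp <- polyOrder + 1L
    yhat0 <- if (linearNonlin) alpha0[1] + alpha0[2] * phi0
             else gfun(phi0)
    res0 <- ytr - yhat0
    s0 <- max(stats::sd(res0), 1e-3)
    nc0 <- switch(noise,
      gaussian = c(log(s0), rep(0, polyOrder)),
      cauchy = c(log(max(stats::mad(res0), 1e-3)), rep(0, polyOrder)),
      skewt = c(log(s0 / 1.5), rep(0, polyOrder),
                log(3), rep(0, polyOrder),
                log(3), rep(0, polyOrder)),
      empirical = numeric(0))
    pvec <- c(theta0, alpha0, nc0)
    idxTheta <- seq_len(pTheta)
    idxAlpha <- pTheta + seq_len(nAlpha)
    idxNoise <- if (length(nc0)) pTheta + nAlpha + seq_along(nc0)
                else integer(0)
  } else {
    freqs <- colSums(Ctr) / sum(Ctr)
    aInit <- log(freqs + 1e-6)
    gridY <- seq(-2, 2, length.out = mpaK)
    eta0 <- c(aInit,
              stats::rnorm(Y * mpaK, sd = 0.1),        # b
              rep(1, Y * mpaK),                        # c
              rep(-gridY, each = Y))                   # d
    pvec <- c(theta0, eta0)
    idxTheta <- seq_len(pTheta)
    idxEta <- pTheta + seq_along(eta0)
  }

  # ---- loss / gradient ---------------------------------------------------
  hY <- if (process == "ge") 1e-4 * scY else 0
  hN <- 1e-5

  phi_of <- function(theta, rows, want = FALSE) {
    if (linearGP) {
      list(phi = as.vector(Dtr[rows, , drop = FALSE] %*% theta))
    } else if (gpKind == "blackbox") {
      w <- .mlp_unpack(gp@weights, theta)
      fw <- .mlp_forward(w, Dtr[rows, , drop = FALSE], gp@activation)
      list(phi = fw$phi, acts = fw$acts, w = w)
    } else {
      prm <- gp@params; prm[] <- theta
      list(phi = gp@phiFun(prm, prepTr)[rows], prm = prm)
    }
  }

  theta_grad <- function(fw, theta, rows, dNLLdphi) {
    if (linearGP) {
      as.vector(crossprod(Dtr[rows, , drop = FALSE], dNLLdphi))
    } else if (gpKind == "blackbox") {
      gr <- .mlp_backward(fw$w, fw$acts, dNLLdphi, gp@activation)
      .mlp_pack(gr)
    } else {
      dfull <- numeric(nTr)
      dfull[rows] <- dNLLdphi
      .custom_grad(gp, prepTr, fw$prm, dfull)
    }
  }

  if (process == "ge") {
    tr_b <- function(x) if (monotonic) .softplus(x) else x
    tr_g <- function(x) if (monotonic) .sigmoid(x) else rep(1, length(x))
    loss_grad <- function(pvec, rows) {
      nB <- length(rows)
      scale <- nTr / nB
      theta <- pvec[idxTheta]
      fw <- phi_of(theta, rows)
      phiB <- fw$phi
      al <- pvec[idxAlpha]
      nc <- pvec[idxNoise]
      if (linearNonlin) {
        yhat <- al[1] + al[2] * phiB
        gpr <- rep(al[2], nB)
      } else {
        b <- tr_b(al[2:(K + 1)]); cc <- tr_b(al[(K + 2):(2 * K + 1)])
        dd <- al[(2 * K + 2):(3 * K + 1)]
        Z <- outer(phiB, cc) + matrix(dd, nB, K, byrow = TRUE)
        Tm <- tanh(Z); V <- 1 - Tm^2
        yhat <- al[1] + as.vector(Tm %*% b)
        gpr <- as.vector(V %*% (b * cc))
      }
      nz <- .make_noise(noise, nc, polyOrder)
      yB <- ytr[rows]
      seB <- if (!is.null(setr)) setr[rows] else NULL
      ll <- noiseLogPdf(nz, yB, yhat, seB)
      ll[!is.finite(ll) | ll < -690] <- -690
      dlp <- .dlp_dyhat(nz, yB, yhat, seB, hY)
      grad <- numeric(length(pvec))
      # theta
      grad[idxTheta] <- scale * theta_grad(fw, theta, rows, -dlp * gpr)
      # alpha
      if (linearNonlin) {
        grad[idxAlpha] <- scale * c(-sum(dlp), -sum(dlp * phiB))
      } else {
        ga <- -sum(dlp)
        gb <- -as.vector(crossprod(Tm, dlp)) * tr_g(al[2:(K + 1)])
        gc <- -as.vector(crossprod(V * phiB, dlp)) * b *
          tr_g(al[(K + 2):(2 * K + 1)])
        gd <- -as.vector(crossprod(V, dlp)) * b
        grad[idxAlpha] <- scale * c(ga, gb, gc, gd)
      }
      # noise coefficients (few; vectorized numeric derivative)
      if (length(idxNoise)) {
        gn <- numeric(length(idxNoise))
        for (j in seq_along(idxNoise)) {
          np <- nc; np[j] <- np[j] + hN
          nm <- nc; nm[j] <- nm[j] - hN
          gn[j] <- -(sum(noiseLogPdf(.make_noise(noise, np, polyOrder),
                                     yB, yhat, seB)) -
                     sum(noiseLogPdf(.make_noise(noise, nm, polyOrder),
                                     yB, yhat, seB))) / (2 * hN)
        }
        grad[idxNoise] <- scale * gn
      }
      # penalties (on transformed eta values)
      grad[idxTheta] <- grad[idxTheta] + 2 * lambdaTheta * theta
      if (linearNonlin) {
        etaVals <- c(al, nc)
        grad[idxAlpha] <- grad[idxAlpha] + 2 * lambdaEta * al
      } else {
        etaVals <- c(al[1], b, cc, dd, nc)
        grad[idxAlpha] <- grad[idxAlpha] + 2 * lambdaEta *
          c(al[1], b * tr_g(al[2:(K + 1)]),
            cc * tr_g(al[(K + 2):(2 * K + 1)]), dd)
      }
      if (length(idxNoise))
        grad[idxNoise] <- grad[idxNoise] + 2 * lambdaEta * nc
      loss <- -scale * sum(ll) + lambdaTheta * sum(theta^2) +
        lambdaEta * sum(etaVals^2)
      list(loss = loss, grad = grad)
    }
    nll_eval <- function(pvec, rows, design = "train") {
      theta <- pvec[idxTheta]
      phiB <- if (design == "train") phi_of(theta, rows)$phi
        else if (linearGP) as.vector(Dva %*% theta)
        else if (gpKind == "blackbox")
          .mlp_forward(.mlp_unpack(gp@weights, theta), Dva,
                       gp@activation)$phi
        else { prm <- gp@params; prm[] <- theta; gp@phiFun(prm, prepVa) }
      al <- pvec[idxAlpha]
      if (linearNonlin) yhat <- al[1] + al[2] * phiB
      else {
        b <- tr_b(al[2:(K + 1)]); cc <- tr_b(al[(K + 2):(2 * K + 1)])
        dd <- al[(2 * K + 2):(3 * K + 1)]
        yhat <- al[1] +
          as.vector(tanh(outer(phiB, cc) +
            matrix(dd, length(phiB), K, byrow = TRUE)) %*% b)
      }
      nz <- .make_noise(noise, pvec[idxNoise], polyOrder)
      yy <- if (design == "train") ytr[rows] else yva
      ss <- if (design == "train") {
        if (!is.null(setr)) setr[rows] else NULL
      } else seva
      ll <- noiseLogPdf(nz, yy, yhat, ss)
      ll[!is.finite(ll) | ll < -690] <- -690
      -sum(ll)
    }
  } else {
    # ---- MPA -------------------------------------------------------------
    unpack_eta <- function(eta) {
      list(a = eta[seq_len(Y)],
           B = matrix(eta[Y + seq_len(Y * mpaK)], Y, mpaK),
           Cc = matrix(eta[Y + Y * mpaK + seq_len(Y * mpaK)], Y, mpaK),
           Dd = matrix(eta[Y + 2L * Y * mpaK + seq_len(Y * mpaK)], Y, mpaK))
    }
    mpa_p <- function(et, phiB) {
      nB <- length(phiB)
      logw <- matrix(rep(et$a, each = nB), nB, Y)
      Tarr <- vector("list", Y)
      for (y in seq_len(Y)) {
        Zy <- outer(phiB, et$Cc[y, ]) +
          matrix(et$Dd[y, ], nB, mpaK, byrow = TRUE)
        Tarr[[y]] <- tanh(Zy)
        logw[, y] <- logw[, y] + as.vector(Tarr[[y]] %*% et$B[y, ])
      }
      mx <- apply(logw, 1, max)
      w <- exp(logw - mx)
      list(p = w / rowSums(w), Tarr = Tarr)
    }
    loss_grad <- function(pvec, rows) {
      nB <- length(rows)
      scale <- nTr / nB
      theta <- pvec[idxTheta]
      fw <- phi_of(theta, rows)
      phiB <- fw$phi
      et <- unpack_eta(pvec[idxEta])
      mp <- mpa_p(et, phiB)
      p <- mp$p
      Cb <- Ctr[rows, , drop = FALSE]
      Nb <- Ntr[rows]
      ll <- sum(Cb * log(pmax(p, 1e-300)))
      Dm <- Cb - Nb * p
      ga <- -colSums(Dm)
      gB <- matrix(0, Y, mpaK); gC <- gB; gD <- gB
      dphi <- numeric(nB)
      for (y in seq_len(Y)) {
        Ty <- mp$Tarr[[y]]; Vy <- 1 - Ty^2
        gB[y, ] <- -as.vector(crossprod(Ty, Dm[, y]))
        gC[y, ] <- -as.vector(crossprod(Vy * phiB, Dm[, y])) * et$B[y, ]
        gD[y, ] <- -as.vector(crossprod(Vy, Dm[, y])) * et$B[y, ]
        dphi <- dphi + Dm[, y] * as.vector(Vy %*% (et$B[y, ] * et$Cc[y, ]))
      }
      grad <- numeric(length(pvec))
      grad[idxTheta] <- scale * theta_grad(fw, theta, rows, -dphi) +
        2 * lambdaTheta * theta
      grad[idxEta] <- scale * c(ga, as.vector(gB), as.vector(gC),
                                as.vector(gD)) +
        2 * lambdaEta * pvec[idxEta]
      loss <- -scale * ll + lambdaTheta * sum(theta^2) +
        lambdaEta * sum(pvec[idxEta]^2)
      list(loss = loss, grad = grad)
    }
    nll_eval <- function(pvec, rows, design = "train") {
      theta <- pvec[idxTheta]
      phiB <- if (design == "train") phi_of(theta, rows)$phi
        else if (linearGP) as.vector(Dva %*% theta)
        else if (gpKind == "blackbox")
          .mlp_forward(.mlp_unpack(gp@weights, theta), Dva,
                       gp@activation)$phi
        else { prm <- gp@params; prm[] <- theta; gp@phiFun(prm, prepVa) }
      et <- unpack_eta(pvec[idxEta])
      p <- mpa_p(et, phiB)$p
      Cb <- if (design == "train") Ctr[rows, , drop = FALSE] else Cva
      -sum(Cb * log(pmax(p, 1e-300)))
    }
  }

  # ---- Adam loop ---------------------------------------------------------
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  mAd <- vAd <- numeric(length(pvec))
  step <- 0L
  bestVal <- Inf; bestP <- pvec; wait <- 0L
  hist <- vector("list", epochs)
  nBatches <- max(1L, ceiling(nTr / batchSize))
  log2e <- log2(exp(1))
  Hy <- if (process == "ge") {
    knnEntropy(ytr, k = 5L)
  } else {
    fq <- colSums(Ctr) / sum(Ctr)
    -sum(ifelse(fq > 0, fq * log2(fq), 0))
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nTr)
    for (bi in seq_len(nBatches)) {
      rows <- ord[seq.int((bi - 1L) * batchSize + 1L,
                          min(bi * batchSize, nTr))]
      lg <- loss_grad(pvec, rows)
      if (!all(is.finite(lg$grad)) || !is.finite(lg$loss))
        stop("non-finite loss/gradient at epoch ", ep,
             "; try a smaller learning rate")
      step <- step + 1L
      mAd <- b1 * mAd + (1 - b1) * lg$grad
      vAd <- b2 * vAd + (1 - b2) * lg$grad^2
      pvec <- pvec - learnRate * (mAd / (1 - b1^step)) /
        (sqrt(vAd / (1 - b2^step)) + epsA)
    }
    trNll <- nll_eval(pvec, seq_len(nTr), "train")
    vaNll <- nll_eval(pvec, NULL, "val")
    hist[[ep]] <- c(epoch = ep, loss = trNll, valLoss = vaNll,
                    Ivar = Hy - log2e * trNll / nObsTr)
    if (vaNll < bestVal - 1e-7) {
      bestVal <- vaNll; bestP <- pvec; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
    if (verbose && ep %% 25L == 0L)
      message(sprintf("epoch %d: train NLL %.2f, val NLL %.2f",
                      ep, trNll, vaNll))
  }
  pvec <- bestP
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))

  # ---- assemble the fitted model ----------------------------------------
  theta <- pvec[idxTheta]
  if (linearGP) {
    gpFit <- switch(gpKind,
      additive = additiveGPMap(L, alph),
      neighbor = neighborGPMap(L, alph),
      pairwise = pairwiseGPMap(L, alph))
    gpFit <- .gp_unpack(gpFit, theta)
  } else if (gpKind == "blackbox") {
    gpFit <- gp
    gpFit@weights <- .mlp_unpack(gp@weights, theta)
  } else {
    gpFit <- gp
    gpFit@params[] <- theta
  }
  if (process == "ge") {
    al <- pvec[idxAlpha]
    nonlin <- if (linearNonlin)
      geNonlinearity(al[1], al[2], kind = "linear", monotonic = FALSE)
    else {
      tr_bv <- if (monotonic) .softplus else identity
      geNonlinearity(al[1], tr_bv(al[2:(K + 1)]),
                     tr_bv(al[(K + 2):(2 * K + 1)]),
                     al[(2 * K + 2):(3 * K + 1)], monotonic = monotonic)
    }
    meas <- geMeasurement(nonlin,
                          .make_noise(noise, pvec[idxNoise], polyOrder))
  } else {
    eta <- pvec[idxEta]
    meas <- mpaMeasurement(Y, mpaK,
      a = eta[seq_len(Y)],
      b = matrix(eta[Y + seq_len(Y * mpaK)], Y, mpaK),
      c = matrix(eta[Y + Y * mpaK + seq_len(Y * mpaK)], Y, mpaK),
      d = matrix(eta[Y + 2L * Y * mpaK + seq_len(Y * mpaK)], Y, mpaK))
  }
  model <- latentModel(gpFit, meas)
  model@history <- history
  model@split <- sp
  model@config <- list(gpmap = gpKind, process = process, noise = noise,
    K = K, mpaK = mpaK, polyOrder = polyOrder, lambdaTheta = lambdaTheta,
    lambdaEta = lambdaEta, split = split, epochs = epochs,
    batchSize = batchSize, learnRate = learnRate, patience = patience,
    seed = seed, gauge = gauge, wildtype = wildtype,
    monotonic = monotonic, linearNonlin = linearNonlin, hidden = hidden)

  # gauge fixing: diffeomorphic always (except custom), hierarchical for
  # parametric maps
  if (!isCustom) {
    trainPhi <- phi(model@gpmap, seqs[trainRows])
    model <- fixDiffeomorphic(model, trainPhi)
    if (linearGP) {
      pG <- switch(gauge,
        uniform = gaugeDistribution(L, alph, "uniform"),
        empirical = gaugeDistribution(L, alph, "empirical",
                                      sequences = seqs[trainRows]),
        wildtype = {
          if (is.null(wildtype)) stop("wildtype gauge needs 'wildtype'")
          gaugeDistribution(L, alph, "wildtype", wildtype = wildtype)
        })
      model@gpmap <- hierarchicalGauge(model@gpmap, pG)
      model@gauge <- gauge
      # effects never observed in training are undefined, not zero
      obs <- colSums(oneHotEncode(seqs[trainRows], alph)) > 0
      mask <- matrix(!obs, L, alphabetSize(alph), byrow = TRUE)
      if (any(mask)) model@gpmap@thetaLC[mask] <- NA_real_
    }
  }
  model
}
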