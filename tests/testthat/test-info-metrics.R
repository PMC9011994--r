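test_that("kNN entropy matches closed forms at moderate n", {
  set.seed(91)
  # differential entropies: uniform(0,1) -> 0 bits; N(0,1) -> 2.047 bits
  expect_equal(knnEntropy(runif(4000)), 0, tolerance = 0.06)
  expect_equal(knnEntropy(rnorm(4000)), 0.5 * log2(2 * pi * exp(1)),
               tolerance = 0.06)
  # scaling by 2 adds exactly one bit (same sample)
  x <- rnorm(1500)
  expect_equal(knnEntropy(2 * x) - knnEntropy(x), 1, tolerance = 0.02)
  expect_error(knnEntropy(rnorm(4), k = 5), "n > k")
  # duplicate-heavy samples are handled by tie-break jitter
  expect_true(is.finite(knnEntropy(rep(c(1, 2, 2.5), 200))))
})

test_that("KSG mutual information matches closed forms and properties", {
  set.seed(93)
  n <- 4000
  x <- rnorm(n)
  # independence: MI ~ 0
  expect_equal(as.numeric(ksgMutualInformation(x, rnorm(n))), 0,
               tolerance = 0.03)
  # bivariate Gaussian rho = 0.8
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  expect_equal(as.numeric(ksgMutualInformation(x, y)),
               -0.5 * log2(1 - 0.64), tolerance = 0.07)
  # invariance under strictly monotone transform of one argument
  expect_equal(as.numeric(ksgMutualInformation(x, y)),
               as.numeric(ksgMutualInformation(exp(x), y)),
               tolerance = 0.05)
  # constant input floors at zero with a warning
  expect_warning(z <- ksgMutualInformation(rep(1, 100), rnorm(100)),
                 "constant")
  expect_equal(as.numeric(z), 0)
  # negative raw estimates are floored but preserved as attribute
  set.seed(94)
  v <- ksgMutualInformation(rnorm(50), rnorm(50))
  expect_gte(as.numeric(v), 0)
  expect_true(is.numeric(attr(v, "raw")))
  expect_error(ksgMutualInformation(x, y, gaoCorrection = TRUE),
               "not implemented")
})

test_that("half-sample uncertainties behave like standard errors", {
  set.seed(95)
  # constant estimator: zero uncertainty
  expect_equal(subsampleUncertainty(function(d) 42, rnorm(100)), 0)
  # sample-mean estimator: dE ~ sd/sqrt(n), shrinking ~ n^{-1/2}
  d1 <- rnorm(400); d2 <- rnorm(6400)
  e1 <- subsampleUncertainty(mean, d1, R = 200)
  e2 <- subsampleUncertainty(mean, d2, R = 200)
  expect_equal(e1, 1 / sqrt(400), tolerance = 0.35)
  expect_equal(e1 / e2, 4, tolerance = 1.2)
  expect_error(subsampleUncertainty(mean, rnorm(3)), "too few")
  expect_error(subsampleUncertainty(mean, rnorm(100), R = 1))
})

test_that("predictive information is zero for a constant map and grows as
           noise shrinks", {
  set.seed(97)
  gpConst <- additiveGPMap(4, dnaAlph, theta0 = 2)
  seqs <- randomSequences(600, 4, dnaAlph)
  d <- MaveDataset(seqs, y = rnorm(600))
  suppressWarnings(ipc <- predictiveInformation(gpConst, d, R = 0))
  expect_equal(ipc$I, 0, tolerance = 1e-9)
  gp <- makeAdditiveTruth(4, seed = 99)
  phiV <- phi(gp, seqs)
  iLow <- predictiveInformation(gp,
    MaveDataset(seqs, y = phiV + rnorm(600, sd = 1)), R = 0)$I
  iHigh <- predictiveInformation(gp,
    MaveDataset(seqs, y = phiV + rnorm(600, sd = 0.3)), R = 0)$I
  expect_gt(iHigh, iLow)
  # closed-form check: y = phi + noise is a Gaussian channel
  sdP <- sd(phiV)
  rho2 <- sdP^2 / (sdP^2 + 1)
  expect_equal(iLow, -0.5 * log2(1 - rho2), tolerance = 0.12)
  # I_pre ignores the measurement process parameters entirely
  m1 <- latentModel(gp, geMeasurement(geNonlinearity(0, 1, 1, 0),
                                      gaussianNoise(0)))
  m2 <- latentModel(gp, geMeasurement(geNonlinearity(5, 2, 3, 1),
                                      cauchyNoise(1)))
  dTest <- MaveDataset(seqs, y = phiV + rnorm(600, sd = 0.5))
  set.seed(1); a <- predictiveInformation(m1, dTest, R = 0)$I
  set.seed(1); b <- predictiveInformation(m2, dTest, R = 0)$I
  expect_equal(a, b)
  expect_error(predictiveInformation(gp, d[1:5], k = 5), "too small")
})

test_that("variational information tracks the analytic channel", {
  set.seed(103)
  # Gaussian channel with the true model supplied: I_var ~ I closed form
  gp <- makeAdditiveTruth(5, seed = 105)
  seqs <- randomSequences(2000, 5, dnaAlph)
  phiV <- phi(gp, seqs)
  s <- 0.8
  y <- phiV + rnorm(2000, sd = s)
  truth <- latentModel(gp, geMeasurement(
    geNonlinearity(0, 1, kind = "linear", monotonic = FALSE),
    gaussianNoise(log(s))))
  d <- MaveDataset(seqs, y = y)
  iv <- variationalInformation(truth, d)
  closed <- 0.5 * log2(1 + var(phiV) / s^2)
  expect_equal(iv$I, closed, tolerance = 3 * iv$dI + 0.05)
  # a model predicting only the marginal has I_var ~ 0
  flat <- latentModel(additiveGPMap(5, dnaAlph),
    geMeasurement(geNonlinearity(mean(y), 1e-12, 1, 0),
                  gaussianNoise(log(sd(y)))))
  iv0 <- variationalInformation(flat, d)
  expect_equal(iv0$I, 0, tolerance = 0.1)
  # constant per-datum density (all y at the mode): var(Q) = 0, dI = dHy
  dConst <- MaveDataset(seqs[1:100],
                        y = rep(evalNonlinearity(flat@measurement@nonlin,
                                                 0), 100))
  ivc <- variationalInformation(flat, dConst, R = 5)
  expect_equal(ivc$dI, ivc$dHy, tolerance = 1e-12)
})

test_that("the intrinsic-information upper bound follows the count formulas", {
  # delta_y for zero counts and the Gaussian conditional entropy
  r <- intrinsicInfoUpper(rnorm(200), cIn = rep(0, 200), cOut = rep(0, 200),
                          R = 0)
  dy0 <- log2(exp(1)) * sqrt(2)
  expect_equal(dy0, 2.0404, tolerance = 1e-4)
  expect_equal(r$meanHxy, 0.5 * log2(2 * pi * exp(1) * dy0^2))
  # delta_y = 1 gives H_x[y] = 2.047 bits
  expect_equal(0.5 * log2(2 * pi * exp(1) * 1^2), 2.047, tolerance = 1e-3)
  expect_error(intrinsicInfoUpper(rnorm(10)), "required")
  # growing counts push the conditional entropy toward -Inf (bound grows)
  rBig <- intrinsicInfoUpper(rnorm(200), rep(1e6, 200), rep(1e6, 200),
                             R = 0)
  dyBig <- log2(exp(1)) * sqrt(2 / (1e6 + 1))
  expect_equal(rBig$meanHxy, 0.5 * log2(2 * pi * exp(1) * dyBig^2))
  expect_gt(rBig$bound, r$bound)
})

test_that("intrinsic-information lower bounds use replicates or models", {
  set.seed(109)
  x <- rnorm(800)
  y <- x + rnorm(800, sd = 0.5)
  y2 <- x + rnorm(800, sd = 0.5)
  r <- intrinsicInfoLower(y, yReplicate = y2, R = 5)
  expect_equal(r$source, "replicate")
  expect_gt(r$bound, 0.5)
  # independent replicates give ~ 0
  r0 <- intrinsicInfoLower(y, yReplicate = rnorm(800), R = 5)
  expect_lt(r0$bound, 0.1)
  # model route: takes the larger bound
  rm <- intrinsicInfoLower(y, yReplicate = rnorm(800),
                           modelIpre = list(I = 1.2, dI = 0.05))
  expect_equal(rm$source, "model")
  expect_equal(rm$bound, 1.2)
  expect_error(intrinsicInfoLower(y), "replicate")
})
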