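test_that("the heteroscedastic scale is an exponentiated polynomial", {
  expect_equal(noiseScale(c(-3, 0, 5), 0), rep(1, 3))
  expect_equal(noiseScale(0.7, log(2)), 2)
  expect_equal(noiseScale(-1, c(0, 1)), exp(-1))
  # clipping keeps the scale finite and positive
  expect_true(is.finite(noiseScale(100, c(0, 10))))
  expect_gt(noiseScale(-100, c(0, 10)), 0)
})

test_that("Gaussian density and quantiles follow the closed forms", {
  nz <- gaussianNoise(0)  # s = 1
  expect_equal(noiseLogPdf(nz, 0.3, 0.3), -0.5 * log(2 * pi))
  expect_equal(noiseQuantile(nz, 0.5, 1.7), 1.7)
  # quantile(CDF(y)) = y on a grid
  y <- seq(-3, 3, length.out = 21)
  expect_equal(noiseQuantile(nz, noiseCdf(nz, y, 0.5), rep(0.5, 21)), y,
               tolerance = 1e-9)
  expect_error(noiseQuantile(nz, 1.2, 0), "0, 1")
})

test_that("Cauchy quantiles are exact", {
  nz <- cauchyNoise(log(2))  # s = 2
  expect_equal(noiseQuantile(nz, 0.5, 1), 1)
  expect_equal(noiseQuantile(nz, 0.75, 1), 1 + 2)
  expect_equal(exp(noiseLogPdf(nz, 1, 1)), 1 / (pi * 2))
  y <- seq(-5, 5, length.out = 11)
  expect_equal(noiseQuantile(nz, noiseCdf(nz, y, 0), rep(0, 11)), y,
               tolerance = 1e-9)
})

test_that("all three noise densities integrate to 1", {
  cases <- list(gaussianNoise(log(0.7)), cauchyNoise(log(0.5)),
                skewTNoise(log(0.8), log(2), log(3)),
                skewTNoise(log(1.2), log(6), log(6)))
  for (nz in cases) {
    f <- function(y) exp(noiseLogPdf(nz, y, 0.4))
    z <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-9,
                          subdivisions = 2000L)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("skew-t mode sits at yhat and symmetry holds for a = b", {
  # symmetric case: median and mode at yhat
  nz <- skewTNoise(log(0.5), log(3), log(3))
  expect_equal(noiseQuantile(nz, 0.5, 2), 2, tolerance = 1e-9)
  y <- seq(-2, 2, length.out = 9)
  expect_equal(noiseLogPdf(nz, 2 + y, 2), noiseLogPdf(nz, 2 - y, 2),
               tolerance = 1e-9)
  # mode at yhat by numerical maximization, random skewed parameters
  set.seed(51)
  for (r in 1:5) {
    nz <- skewTNoise(log(runif(1, 0.3, 2)), log(runif(1, 0.7, 5)),
                     log(runif(1, 0.7, 5)))
    opt <- stats::optimize(function(y) noiseLogPdf(nz, y, 1.3),
                           interval = c(-40, 40), maximum = TRUE,
                           tol = 1e-9)
    expect_equal(opt$maximum, 1.3, tolerance = 1e-5)
  }
})

test_that("skew-t quantiles invert the CDF", {
  nz <- skewTNoise(log(0.9), log(2), log(5))
  q <- c(0.01, 0.1, 0.3, 0.5, 0.8, 0.99)
  yq <- noiseQuantile(nz, q, rep(0.7, length(q)))
  expect_equal(noiseCdf(nz, yq, rep(0.7, length(q))), q, tolerance = 1e-8)
  y <- seq(-4, 4, length.out = 15)
  expect_equal(noiseQuantile(nz, noiseCdf(nz, y, 0), rep(0, 15)), y,
               tolerance = 1e-7)
})

test_that("skew-t approaches the Gaussian as a = b grow", {
  # KL divergence to the matching Gaussian shrinks monotonically
  yg <- seq(-6, 6, length.out = 2001)
  kl <- vapply(c(3, 10, 40, 150), function(ab) {
    nz <- skewTNoise(0, log(ab), log(ab))
    lp <- noiseLogPdf(nz, yg, 0)
    p <- exp(lp) / sum(exp(lp))
    sdEmp <- sqrt(sum(p * yg^2))
    lq <- dnorm(yg, 0, sdEmp, log = TRUE)
    q <- exp(lq) / sum(exp(lq))
    sum(p * (log(p) - log(q)))
  }, 0)
  expect_true(all(diff(kl) < 0))
  expect_lt(kl[4], 1e-4)
})

test_that("empirical noise is Gaussian with fixed per-datum scale", {
  nz <- empiricalNoise()
  expect_equal(noiseLogPdf(nz, 1.2, 1.0, se = 0.3),
               dnorm(1.2, 1.0, 0.3, log = TRUE))
  # doubling s_n lowers the log density at the mode by ln 2
  expect_equal(noiseLogPdf(nz, 1, 1, se = 0.2) -
               noiseLogPdf(nz, 1, 1, se = 0.4), log(2))
  expect_error(noiseLogPdf(nz, 1, 1), "standard errors")
  # s_n -> 0 concentrates mass at yhat
  expect_gt(noiseLogPdf(nz, 1, 1, se = 1e-8),
            noiseLogPdf(nz, 1, 1, se = 1e-4))
})

test_that("prediction intervals come from noise quantiles around g(phi)", {
  meas <- geMeasurement(geNonlinearity(0, 2, 1, 0), gaussianNoise(log(0.5)))
  pi95 <- predictionInterval(meas, c(-1, 0, 1), 0.025, 0.975)
  expect_equal(pi95$yhat, 2 * tanh(c(-1, 0, 1)))
  # symmetric Gaussian: centered on yhat
  expect_equal(pi95$yhat - pi95$yLo, pi95$yHi - pi95$yhat)
  expect_equal(pi95$yHi - pi95$yLo, rep(2 * qnorm(0.975) * 0.5, 3))
  expect_error(predictionInterval(meas, 0, 0.9, 0.1))
  measE <- geMeasurement(geNonlinearity(), empiricalNoise())
  expect_error(predictionInterval(measE, 0), "se")
})

test_that("prediction interval coverage matches the nominal level", {
  set.seed(57)
  nz <- skewTNoise(log(0.6), log(2), log(4))
  yhat <- rep(0.5, 1e4)
  y <- noiseSample(nz, yhat)
  lo <- noiseQuantile(nz, 0.025, yhat)
  hi <- noiseQuantile(nz, 0.975, yhat)
  expect_equal(mean(y >= lo & y <= hi), 0.95, tolerance = 0.02)
})
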