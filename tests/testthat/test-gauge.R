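test_that("gauge distributions are valid probability matrices", {
  p <- gaugeDistribution(3, dnaAlph, "uniform")
  expect_equal(rowSums(p), rep(1, 3))
  seqs <- c("ACG", "ACG", "TCG", "AAG")
  pe <- gaugeDistribution(3, dnaAlph, "empirical", sequences = seqs)
  expect_equal(pe[1, ], c(0.75, 0, 0, 0.25))
  expect_equal(rowSums(pe), rep(1, 3))
  pw <- gaugeDistribution(3, dnaAlph, "wildtype", wildtype = "ACG")
  expect_equal(pw[2, ], c(0, 1, 0, 0))
  expect_error(gaugeDistribution(3, dnaAlph, "empirical"), "sequences")
})

test_that("hierarchical gauge matches the hand-computed L=1, C=2 case", {
  gp <- additiveGPMap(1, Alphabet("AB"), theta0 = 0,
                      thetaLC = matrix(c(2, 4), 1))
  g <- hierarchicalGauge(gp)
  expect_equal(g@theta0, 3)
  expect_equal(as.vector(g@thetaLC), c(-1, 1))
  expect_equal(phi(g, "A"), 2)  # phi preserved
})

test_that("hierarchical gauge preserves phi, is idempotent, zeroes marginals", {
  set.seed(23)
  L <- 5
  gp <- pairwiseGPMap(L, dnaAlph, theta0 = rnorm(1),
                      thetaLC = matrix(rnorm(L * 4), L, 4))
  gp@thetaPairs <- rnorm(length(gp@thetaPairs))
  seqs <- randomSequences(1000, L, dnaAlph)
  for (src in c("uniform", "empirical")) {
    p <- gaugeDistribution(L, dnaAlph, src, sequences = seqs)
    g <- hierarchicalGauge(gp, p)
    expect_lt(max(abs(phi(g, seqs) - phi(gp, seqs))), 1e-9)
    g2 <- hierarchicalGauge(g, p)
    expect_lt(max(abs(latentmave:::.gp_pack(g2) -
                      latentmave:::.gp_pack(g))), 1e-9)
    # p-weighted marginals vanish: additive per position, pairs both ways
    expect_lt(max(abs(rowSums(g@thetaLC * p))), 1e-10)
    C <- 4
    for (k in seq_len(nrow(g@pairs))) {
      M <- matrix(g@thetaPairs[((k - 1) * C^2 + 1):(k * C^2)], C, C,
                  byrow = TRUE)
      l <- g@pairs[k, 1] + 1; lp <- g@pairs[k, 2] + 1
      expect_lt(max(abs(p[l, ] %*% M)), 1e-10)
      expect_lt(max(abs(M %*% p[lp, ])), 1e-10)
    }
  }
  # wildtype gauge zeroes wildtype effects and anchors phi(WT) at theta0
  wt <- seqs[1]
  pw <- gaugeDistribution(L, dnaAlph, "wildtype", wildtype = wt)
  gw <- hierarchicalGauge(gp, pw)
  idx <- latentmave:::.seq_to_idx(wt, dnaAlph)[1, ]
  expect_equal(max(abs(gw@thetaLC[cbind(1:L, idx)])), 0)
  expect_equal(phi(gw, wt), gw@theta0)
})

test_that("hierarchical gauge minimizes the interaction-part variance", {
  # brute force on L=2, C=3: enumerate all sequences; compare the gauged
  # parameterization against random gauge-equivalent ones
  set.seed(31)
  ab <- Alphabet("XYZ")
  L <- 2; C <- 3
  gp <- pairwiseGPMap(L, ab, theta0 = rnorm(1),
                      thetaLC = matrix(rnorm(L * C), L, C))
  gp@thetaPairs <- rnorm(C * C)
  p <- gaugeDistribution(L, ab, "uniform")
  allSeqs <- as.vector(outer(c("X", "Y", "Z"), c("X", "Y", "Z"), paste0))
  wts <- rep(1 / 9, 9)
  pairVar <- function(m) {
    add <- additiveGPMap(L, ab, m@theta0, m@thetaLC)
    v <- phi(m, allSeqs) - phi(add, allSeqs)
    sum(wts * v^2) - sum(wts * v)^2
  }
  g <- hierarchicalGauge(gp, p)
  expect_lt(max(abs(phi(g, allSeqs) - phi(gp, allSeqs))), 1e-9)
  for (r in 1:30) {
    # random gauge mode: move an additive function of one position into
    # the interaction block (leaves phi untouched)
    v <- gp
    u1 <- rnorm(C); u2 <- rnorm(C); lam <- rnorm(L)
    M <- matrix(v@thetaPairs, C, C, byrow = TRUE) +
      outer(u1, rep(1, C)) + outer(rep(1, C), u2)
    v@thetaPairs <- as.vector(t(M))
    v@thetaLC[1, ] <- v@thetaLC[1, ] - u1 + lam[1]
    v@thetaLC[2, ] <- v@thetaLC[2, ] - u2 + lam[2]
    v@theta0 <- v@theta0 - sum(lam)
    expect_lt(max(abs(phi(v, allSeqs) - phi(gp, allSeqs))), 1e-9)
    expect_lte(pairVar(g), pairVar(v) + 1e-12)
  }
})

test_that("diffeomorphic fixing standardizes phi without changing p(y|x)", {
  set.seed(37)
  truth <- makeGETruth(L = 5, noise = gaussianNoise(c(log(0.4), 0.1)),
                       seed = 41)
  # un-standardized model: inflate theta, shift theta0
  m <- truth
  m@gpmap@theta0 <- m@gpmap@theta0 + 10
  m@gpmap@thetaLC <- m@gpmap@thetaLC * 5
  seqs <- randomSequences(400, 5, dnaAlph)
  trainPhi <- phi(m@gpmap, seqs)
  yGrid <- seq(-2, 4, length.out = 7)
  before <- sapply(yGrid, function(y)
    noiseLogPdf(m@measurement@noise, y,
                evalNonlinearity(m@measurement@nonlin, trainPhi)))
  f <- fixDiffeomorphic(m, trainPhi)
  phiNew <- phi(f@gpmap, seqs)
  expect_equal(mean(phiNew), 0, tolerance = 1e-10)
  expect_equal(sd(phiNew), 1, tolerance = 1e-10)
  after <- sapply(yGrid, function(y)
    noiseLogPdf(f@measurement@noise, y,
                evalNonlinearity(f@measurement@nonlin, phiNew)))
  expect_lt(max(abs(exp(before) - exp(after))), 1e-9)
  # already standardized: a = 0, b = 1, model unchanged
  f2 <- fixDiffeomorphic(f, phiNew)
  expect_equal(unname(f2@diffeo), c(0, 1), tolerance = 1e-9)
  expect_equal(f2@gpmap@thetaLC, f@gpmap@thetaLC, tolerance = 1e-9)
  # degenerate map rejected
  expect_error(fixDiffeomorphic(m, rep(1, 10)), "zero variance")
})

test_that("diffeomorphic fixing preserves MPA bin probabilities", {
  truth <- makeMPATruth(L = 4, seed = 43)
  m <- truth
  m@gpmap@theta0 <- 3; m@gpmap@thetaLC <- m@gpmap@thetaLC * 2
  seqs <- randomSequences(300, 4, dnaAlph)
  pBefore <- predictBinProbs(m, seqs)
  f <- fixDiffeomorphic(m, phi(m@gpmap, seqs))
  expect_lt(max(abs(predictBinProbs(f, seqs) - pBefore)), 1e-9)
})
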