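test_that("Boltzmann occupancies match hand-computed states", {
  ab <- dnaAlph
  # three states at energies (0, 1, -1), beta = 1, readout = third
  tm <- thermodynamicModel(
    matrices = list(),
    scalars = c(E1 = 1, E2 = -1),
    states = list(ref = character(0), s1 = "E1", s2 = "E2"),
    readout = "s2", beta = 1)
  occ <- boltzmannOccupancy(tm, "ACGT", ab)
  expect_equal(occ, exp(1) / (1 + exp(-1) + exp(1)), tolerance = 1e-10)
  expect_equal(occ, 0.6652, tolerance = 1e-4)
  # equal energies: phi = |readout| / |states|
  tm0 <- thermodynamicModel(list(), c(E = 0),
    states = list(ref = character(0), s1 = "E", s2 = "E"),
    readout = c("s1", "s2"), beta = 1)
  expect_equal(boltzmannOccupancy(tm0, "ACGT", ab), 2 / 3)
  # occupancy depends only on beta * (energy differences): rescaling beta
  # while inversely rescaling the energies changes nothing
  tmScaled <- thermodynamicModel(list(), c(E1 = 2, E2 = -2),
    states = list(ref = character(0), s1 = "E1", s2 = "E2"),
    readout = "s2", beta = 0.5)
  expect_equal(boltzmannOccupancy(tmScaled, "ACGT", ab), occ,
               tolerance = 1e-12)
  # huge common energies are handled by the log-sum-exp shift
  tmBig <- thermodynamicModel(list(), c(E1 = -2000, E2 = -2002),
    states = list(ref = character(0), s1 = "E1", s2 = "E2"),
    readout = "s2", beta = 1)
  expect_true(is.finite(boltzmannOccupancy(tmBig, "ACGT", ab)))
})

test_that("the GB1-style three-state map behaves thermodynamically", {
  ab <- builtinAlphabet("protein")
  L <- 4
  zero <- matrix(0, L, 20)
  # all energies 0: occupancy of the single readout state is 1/3
  tm <- gb1ThreeState(zero, zero, beta = 1)
  seqs <- c("ACDE", "WYYW")
  expect_equal(boltzmannOccupancy(tm, seqs, ab), c(1, 1) / 3)
  # decreasing binding energy strictly increases occupancy
  occs <- vapply(seq(2, -6, length.out = 9), function(gb)
    boltzmannOccupancy(gb1ThreeState(zero, zero, bindOffset = gb,
                                     beta = 1), "ACDE", ab), 0)
  expect_true(all(diff(occs) > 0))
  # unfolding dominates as folding energy grows
  expect_lt(boltzmannOccupancy(gb1ThreeState(zero, zero, foldOffset = 40,
                                             beta = 1), "ACDE", ab), 1e-10)
  # state occupancies always sum to 1 (readout of all states)
  set.seed(121)
  tmr <- gb1ThreeState(matrix(rnorm(L * 20), L, 20),
                       matrix(rnorm(L * 20), L, 20))
  allStates <- tmr; allStates@readout <- names(tmr@states)
  expect_equal(boltzmannOccupancy(allStates, seqs, ab), c(1, 1))
})

test_that("the lac-style four-state map matches arithmetic and errors", {
  ab <- dnaAlph
  z6 <- matrix(0, 6, 4)
  # all zero energies: phi = 2/4
  tm <- lacFourState(z6, z6, dGI = 0, rnapStart = 6L, beta = 1)
  expect_equal(boltzmannOccupancy(tm, "ACGTACGTACGT", ab), 0.5)
  # dG_C = 0, dG_R = 1, dG_I = -2: phi = (e^-1 + e^1) / (2 + e^-1 + e^1)
  tm2 <- lacFourState(z6, z6, dGI = -2, rnapStart = 6L, rnapOffset = 1,
                      beta = 1)
  expect_equal(boltzmannOccupancy(tm2, "ACGTACGTACGT", ab),
               (exp(-1) + exp(1)) / (1 + 1 + exp(-1) + exp(1)),
               tolerance = 1e-12)
  expect_equal(boltzmannOccupancy(tm2, "ACGTACGTACGT", ab), 0.6068,
               tolerance = 1e-4)
  # strong cooperative recruitment drives phi -> 1
  tm3 <- lacFourState(z6, z6, dGI = -80, rnapStart = 6L, beta = 1)
  expect_gt(boltzmannOccupancy(tm3, "ACGTACGTACGT", ab), 1 - 1e-10)
  # footprint outside the assayed region is rejected
  tmBad <- lacFourState(z6, z6, dGI = 0, rnapStart = 10L)
  expect_error(boltzmannOccupancy(tmBad, "ACGTACGTACGT", ab), "outside")
})

test_that("thermodynamic custom maps expose correct analytic gradients", {
  set.seed(123)
  crp <- matrix(rnorm(12), 3, 4); rnap <- matrix(rnorm(12), 3, 4)
  tm <- lacFourState(crp, rnap, dGI = -2, rnapStart = 3L)
  gp <- thermodynamicGPMap(tm, L = 6, dnaAlph)
  seqs <- randomSequences(40, 6, dnaAlph)
  expect_equal(phi(gp, seqs), boltzmannOccupancy(tm, seqs, dnaAlph))
  prep <- gp@prepare(seqs, dnaAlph)
  dphi <- rnorm(40)
  ga <- gp@gradFun[[1]](gp@params, prep, dphi)
  numeric_gp <- customGPMap(6, dnaAlph, phiFun = gp@phiFun,
                            params = gp@params, prepare = gp@prepare)
  gn <- latentmave:::.custom_grad(numeric_gp, prep, gp@params, dphi)
  expect_equal(ga, gn, tolerance = 1e-6)
})

test_that("a known interaction energy is recovered within bootstrap error", {
  set.seed(131)
  alph <- dnaAlph; L <- 12
  crp <- matrix(rnorm(24), 6, 4); crp <- crp - rowMeans(crp)
  rnap <- matrix(rnorm(24), 6, 4); rnap <- rnap - rowMeans(rnap)
  truthTM <- lacFourState(crp, rnap, dGI = -2.598, rnapStart = 6L,
                          crpOffset = -1, rnapOffset = 1)
  gpTruth <- thermodynamicGPMap(truthTM, L, alph)
  truth <- latentModel(gpTruth, geMeasurement(
    geNonlinearity(0, 1, kind = "linear", monotonic = FALSE),
    gaussianNoise(log(0.05))))
  seqs <- randomSequences(1500, L, alph)
  dat <- simulateDataset(truth, seqs, seed = 19)
  init <- gpTruth
  set.seed(132)
  init@params <- gpTruth@params + rnorm(length(gpTruth@params), sd = 0.3)
  fit <- fitLatentModel(dat, init, noise = "gaussian", K = 3,
                        polyOrder = 0, epochs = 3000, learnRate = 5e-3,
                        seed = 20, patience = 400, lambdaTheta = 0,
                        lambdaEta = 0)
  suppressWarnings(
    bs <- parametricBootstrap(fit, seqs, R = 5, seed = 21, epochs = 800))
  dGI <- fit@gpmap@params[["GI"]]
  se <- bootstrapSE(bs)[["GI"]]
  expect_lt(abs(dGI - (-2.598)), 2 * se)
})
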