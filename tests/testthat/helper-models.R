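# shared builders for small ground-truth models and simulated datasets

dnaAlph <- builtinAlphabet("dna")

makeAdditiveTruth <- function(L = 6, sd = 1, seed = 101,
                              alphabet = dnaAlph) {
  set.seed(seed)
  additiveGPMap(L, alphabet, theta0 = 0,
                thetaLC = matrix(rnorm(L * alphabetSize(alphabet), sd = sd),
                                 L, alphabetSize(alphabet)))
}

makeGETruth <- function(L = 6, noise = gaussianNoise(log(0.3)),
                        nonlin = geNonlinearity(1, 2, 1, 0), seed = 101) {
  latentModel(makeAdditiveTruth(L, seed = seed),
              geMeasurement(nonlin, noise))
}

makeMPATruth <- function(L = 6, Y = 4, seed = 101) {
  gp <- makeAdditiveTruth(L, sd = 0.7, seed = seed)
  meas <- mpaMeasurement(Y, K = 1,
    a = seq(0.3, -0.3, length.out = Y),
    b = matrix(seq(-2, 2, length.out = Y), Y, 1),
    c = matrix(1, Y, 1), d = matrix(0, Y, 1))
  latentModel(gp, meas)
}

simGEData <- function(truth, n = 1000, seed = 1) {
  set.seed(seed)
  seqs <- randomSequences(n, truth@gpmap@L, truth@gpmap@alphabet)
  simulateDataset(truth, seqs, seed = seed + 1)
}

# gauge-fixed flat parameter vector of the truth, standardized on the same
# training phi as a fitted model (so the two are directly comparable)
truthParamsLike <- function(truth, fit, sequences) {
  std <- fixDiffeomorphic(truth, phi(truth@gpmap, sequences[fit@split$train]))
  latentmave:::.gp_pack(hierarchicalGauge(std@gpmap))
}
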