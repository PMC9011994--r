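#' Sequence library generators for simulation
#'
#' \code{randomSequences} draws independent uniform sequences over an
#' alphabet; \code{mutagenizeSequences} applies independent per-position
#' substitutions to a wildtype at a given rate (emulating mutagenic PCR
#' libraries); \code{singleDoubleLibrary} builds the wildtype, all
#' \eqn{L(C-1)} single mutants, and a random sample of distinct double
#' mutants (the design used to study how many multiple-mutation variants
#' are needed to deconvolve experimental nonlinearities). All draw from
#' the current RNG stream; seed with \code{set.seed} for reproducibility.
#'
#' @param n number of sequences.
#' @param L sequence length.
#' @param alphabet an \linkS4class{Alphabet}.
#' @param wildtype reference sequence.
#' @param rate per-position substitution probability in [0, 1].
#' @param nDoubles number of distinct double mutants to sample.
#' @param includeWT include the wildtype itself.
#' @return Character vector of sequences.
#' @export
randomSequences <- function(n, L, alphabet) {
  chars <- alphabet@characters
  m <- matrix(sample(chars, n * L, replace = TRUE), n, L)
  apply(m, 1, paste, collapse = "")
}

#' @rdname randomSequences
#' @export
mutagenizeSequences <- function(wildtype, n, rate, alphabet) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- alphabet@characters
  wt <- strsplit(toupper(wildtype), "")[[1]]
  L <- length(wt)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- wt
    hit <- which(stats::runif(L) < rate)
    for (l in hit) s[l] <- sample(setdiff(chars, s[l]), 1L)
    out[i] <- paste(s, collapse = "")
  }
  out
}

#' @rdname randomSequences
#' @export
singleDoubleLibrary <- function(wildtype, nDoubles, alphabet,
                                includeWT = TRUE) {
  chars <- alphabet@characters
  wt <- strsplit(toupper(wildtype), "")[[1]]
  L <- length(wt)
  singles <- character(0)
  for (l in seq_len(L)) for (ch in setdiff(chars, wt[l])) {
    s <- wt; s[l] <- ch
    singles <- c(singles, paste(s, collapse = ""))
  }
  doubles <- character(0)
  if (nDoubles > 0) {
    maxDoubles <- choose(L, 2) * (length(chars) - 1L)^2
    if (nDoubles > maxDoubles)
      stop("only ", maxDoubles, " distinct double mutants exist for this ",
           "wildtype; requested ", nDoubles)
    seen <- new.env(hash = TRUE)
    while (length(doubles) < nDoubles) {
      ll <- sample.int(L, 2L)
      s <- wt
      s[ll[1]] <- sample(setdiff(chars, wt[ll[1]]), 1L)
      s[ll[2]] <- sample(setdiff(chars, wt[ll[2]]), 1L)
      key <- paste(s, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        doubles <- c(doubles, key)
      }
    }
  }
  c(if (includeWT) paste(wt, collapse = ""), singles, doubles)
}

#' Simulate a MAVE dataset from a latent phenotype model
#'
#' Any latent phenotype model — fitted or hand-built — doubles as a
#' dataset simulator. In GE mode, measurements are drawn from the noise
#' model at \eqn{\hat{y} = g(\phi(x))}; in MPA mode, bins are drawn from
#' \eqn{p(y|\phi(x))}, either one bin per sequence (pair mode) or
#' \code{reads} multinomial draws per sequence (count mode). Deterministic
#' given \code{seed}.
#'
#' @param model a \linkS4class{LatentModel}.
#' @param sequences character vector of sequences over the model's
#'   alphabet.
#' @param reads for MPA models: reads per sequence (count mode); NULL for
#'   one bin per sequence.
#' @param se per-measurement standard errors for the empirical noise
#'   model (recorded in the output as \code{se}).
#' @param seed optional RNG seed.
#' @return A \linkS4class{MaveDataset} in the matching mode.
#' @export
simulateDataset <- function(model, sequences, reads = NULL, se = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alph <- model@gpmap@alphabet
  phiVals <- phi(model@gpmap, sequences)
  if (anyNA(phiVals))
    stop("phi undefined for some sequences; check alphabet/length")
  if (is(model@measurement, "GEMeasurement")) {
    yhat <- evalNonlinearity(model@measurement@nonlin, phiVals)
    y <- noiseSample(model@measurement@noise, yhat, se)
    MaveDataset(sequences, y = y, se = se, alphabet = alph)
  } else {
    P <- mpaProbabilities(model@measurement, phiVals)
    Y <- ncol(P)
    if (is.null(reads)) {
      bins <- vapply(seq_along(sequences), function(i)
        sample.int(Y, 1L, prob = P[i, ]) - 1L, 0L)
      MaveDataset(sequences, bins = bins, alphabet = alph)
    } else {
      cts <- t(vapply(seq_along(sequences), function(i)
        as.integer(stats::rmultinom(1L, reads, P[i, ])), integer(Y)))
      colnames(cts) <- paste0("ct_", 0:(Y - 1L))
      MaveDataset(sequences, counts = cts, alphabet = alph)
    }
  }
}
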