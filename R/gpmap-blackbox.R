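#' Black-box (multilayer perceptron) G-P map
#'
#' A densely connected multilayer perceptron that takes a vector of
#' sequence features (additive one-hot, optionally with neighbor or
#' pairwise products) as input, applies one or more nonlinear hidden
#' layers, and returns a single linear output node as the latent
#' phenotype.
#'
#' @slot inputFeatures which feature set feeds the network: "additive",
#'   "neighbor" or "pairwise".
#' @slot hidden integer vector of hidden-layer sizes (>= 1 layer).
#' @slot activation hidden activation, currently "tanh" or "relu".
#' @slot weights list with one element per layer, each \code{list(W, b)};
#'   the final element is the linear output layer.
#' @export
setClass("BlackBoxGPMap", contains = "GPMap",
  representation(inputFeatures = "character", hidden = "integer",
                 activation = "character", weights = "list"))

setValidity("BlackBoxGPMap", function(object) {
  if (length(object@hidden) < 1L || any(object@hidden < 1L))
    return("need at least one hidden layer of positive size")
  if (!object@activation %in% c("tanh", "relu"))
    return("activation must be 'tanh' or 'relu'")
  if (!object@inputFeatures %in% c("additive", "neighbor", "pairwise"))
    return("inputFeatures must be additive/neighbor/pairwise")
  TRUE
})

#' Construct a black-box G-P map
#'
#' Weights initialize from small zero-mean Gaussian draws scaled by
#' 1/sqrt(fan-in) (seeded); all-zero weights give \eqn{\phi = 0}.
#'
#' @param L sequence length.
#' @param alphabet an \linkS4class{Alphabet}.
#' @param hidden integer vector of hidden-layer sizes.
#' @param inputFeatures feature set fed to the network.
#' @param activation hidden activation function.
#' @param seed RNG seed for weight initialization.
#' @return A \linkS4class{BlackBoxGPMap}.
#' @export
blackboxGPMap <- function(L, alphabet, hidden = c(10, 10),
                          inputFeatures = "additive",
                          activation = "tanh", seed = 1L) {
  C <- alphabetSize(alphabet)
  p <- .bb_input_dim(L, C, inputFeatures)
  dims <- c(p, hidden, 1L)
  set.seed(seed)
  weights <- lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                 sd = 1 / sqrt(dims[i])),
                    dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L]))
  })
  new("BlackBoxGPMap", L = as.integer(L), nchars = as.integer(C),
      alphabet = alphabet, inputFeatures = inputFeatures,
      hidden = as.integer(hidden), activation = activation,
      weights = weights)
}

.bb_input_dim <- function(L, C, inputFeatures) {
  switch(inputFeatures,
    additive = L * C,
    neighbor = L * C + (L - 1L) * C * C,
    pairwise = L * C + L * (L - 1L) / 2L * C * C)
}

.bb_features <- function(map, sequences) {
  X <- oneHotEncode(sequences, map@alphabet)
  if (map@inputFeatures == "additive") return(X)
  cbind(X, pairwiseFeatures(X, neighborOnly = map@inputFeatures == "neighbor"))
}

#' @rdname phi
#' @export
setMethod("phi", "BlackBoxGPMap", function(map, sequences) {
  X <- .bb_features(map, sequences)
  .mlp_forward(map@weights, X, map@activation)$phi
})

#' @rdname nParams
#' @export
setMethod("nParams", "BlackBoxGPMap", function(map) {
  sum(vapply(map@weights, function(w) length(w$W) + length(w$b), 0))
})

setMethod("show", "BlackBoxGPMap", function(object) {
  cat("black-box G-P map: L =", object@L, ", C =", object@nchars,
      "| hidden:", paste(object@hidden, collapse = "-"),
      "(", object@activation, "),", nParams(object), "parameters\n")
})

# ---- MLP forward / backward ---------------------------------------------
.act <- function(z, kind) if (kind == "tanh") tanh(z) else pmax(z, 0)
.act_grad <- function(a, kind) if (kind == "tanh") 1 - a^2 else (a > 0) * 1

.mlp_forward <- function(weights, X, activation = "tanh") {
  nl <- length(weights)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  for (i in seq_len(nl - 1L)) {
    z <- acts[[i]] %*% weights[[i]]$W
    z <- sweep(z, 2, weights[[i]]$b, "+")
    acts[[i + 1L]] <- .act(z, activation)
  }
  out <- acts[[nl]] %*% weights[[nl]]$W + weights[[nl]]$b
  list(phi = as.vector(out), acts = acts)
}

# dphi: vector dL/dphi per row; returns list of grads matching `weights`
.mlp_backward <- function(weights, acts, dphi, activation = "tanh") {
  nl <- length(weights)
  grads <- vector("list", nl)
  delta <- matrix(dphi, ncol = 1L)
  for (i in nl:1L) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(weights[[i]]$W)) *
        .act_grad(acts[[i]], activation)
    }
  }
  grads
}

.mlp_pack <- function(weights)
  unlist(lapply(weights, function(w) c(as.vector(w$W), w$b)))

.mlp_unpack <- function(weights, v) {
  off <- 0L
  for (i in seq_along(weights)) {
    nW <- length(weights[[i]]$W); nb <- length(weights[[i]]$b)
    weights[[i]]$W <- matrix(v[(off + 1L):(off + nW)],
                             nrow(weights[[i]]$W), ncol(weights[[i]]$W))
    off <- off + nW
    weights[[i]]$b <- v[(off + 1L):(off + nb)]
    off <- off + nb
  }
  weights
}
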