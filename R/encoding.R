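#' One-hot encode sequences
#'
#' Encodes each sequence as binary indicator features \eqn{x_{l:c}}, equal to
#' 1 when character \eqn{c} occurs at position \eqn{l} (positions are
#' 0-based, \eqn{l = 0, \dots, L-1}). Feature columns are ordered row-major
#' by position, then by alphabet order, so parameter vectors are portable.
#'
#' @param sequences character vector of equal-length sequences.
#' @param alphabet an \linkS4class{Alphabet}; every character of every
#'   sequence must belong to it (case is normalized to upper case; no
#'   silent U/T conversion).
#' @return A binary matrix with one row per sequence and \eqn{L C} columns
#'   named \code{"l:c"}; each row sums to \eqn{L}. Attributes \code{L} and
#'   \code{C} record the dimensions.
#' @examples
#' oneHotEncode("ACG", builtinAlphabet("dna"))
#' @export
oneHotEncode <- function(sequences, alphabet) {
  idx <- .seq_to_idx(sequences, alphabet)
  n <- nrow(idx); L <- ncol(idx); C <- alphabetSize(alphabet)
  X <- matrix(0L, n, L * C)
  for (l in seq_len(L)) {
    X[cbind(seq_len(n), (l - 1L) * C + idx[, l])] <- 1L
  }
  colnames(X) <- as.vector(t(outer(0:(L - 1L), alphabet@characters, paste,
                                   sep = ":")))
  attr(X, "L") <- L
  attr(X, "C") <- C
  X
}

#' Pairwise interaction features
#'
#' Products \eqn{x_{l:c} x_{l':c'}} for all position pairs with \eqn{l' > l}
#' (the convention used throughout for interaction parameters). With
#' \eqn{L < 2} the feature set is empty. Columns are ordered by
#' \eqn{(l, l')} pair, then row-major by \eqn{(c, c')}.
#'
#' @param onehot a matrix from \code{\link{oneHotEncode}}.
#' @param neighborOnly if \code{TRUE}, keep only adjacent pairs
#'   \eqn{l' = l + 1}.
#' @return Binary matrix with \eqn{L(L-1)/2 \cdot C^2} columns (or
#'   \eqn{(L-1) C^2} when \code{neighborOnly}); each row has one active
#'   feature per retained position pair.
#' @examples
#' x <- oneHotEncode("AT", builtinAlphabet("dna"))
#' sum(pairwiseFeatures(x))
#' @export
pairwiseFeatures <- function(onehot, neighborOnly = FALSE) {
  L <- attr(onehot, "L"); C <- attr(onehot, "C")
  if (is.null(L) || is.null(C)) stop("'onehot' must come from oneHotEncode()")
  pairs <- .position_pairs(L, neighborOnly)
  n <- nrow(onehot)
  out <- matrix(0L, n, nrow(pairs) * C * C)
  cn <- character(ncol(out))
  cols <- colnames(onehot)
  for (p in seq_len(nrow(pairs))) {
    l <- pairs[p, 1]; lp <- pairs[p, 2]
    a <- onehot[, (l * C + 1L):((l + 1L) * C), drop = FALSE]
    b <- onehot[, (lp * C + 1L):((lp + 1L) * C), drop = FALSE]
    # row-major (c, c') within the block
    block <- matrix(0L, n, C * C)
    for (c1 in seq_len(C)) {
      block[, ((c1 - 1L) * C + 1L):(c1 * C)] <- a[, c1] * b
    }
    j <- ((p - 1L) * C * C + 1L):(p * C * C)
    out[, j] <- block
    cn[j] <- as.vector(t(outer(cols[(l * C + 1L):((l + 1L) * C)],
                               cols[(lp * C + 1L):((lp + 1L) * C)],
                               paste, sep = ",")))
  }
  colnames(out) <- cn
  attr(out, "L") <- L; attr(out, "C") <- C
  attr(out, "pairs") <- pairs
  out
}

# matrix of 0-based position pairs (l, l') with l' > l
.position_pairs <- function(L, neighborOnly = FALSE) {
  if (L < 2L) return(matrix(integer(0), 0, 2))
  if (neighborOnly) {
    cbind(0:(L - 2L), 1:(L - 1L))
  } else {
    do.call(rbind, lapply(0:(L - 2L), function(l) cbind(l, (l + 1L):(L - 1L))))
  }
}
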