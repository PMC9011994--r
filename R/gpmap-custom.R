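#' Custom G-P map contract
#'
#' Wraps a user-supplied deterministic latent-phenotype function so it can
#' be plugged into training, simulation and the parametric bootstrap. The
#' function receives the current parameter vector and a "prepared"
#' representation of the sequences (by default the sequences themselves; a
#' custom \code{prepare} can precompute encodings once per fit). An
#' optional analytic gradient function receives additionally the per-datum
#' upstream derivative \eqn{\partial L / \partial \phi_n} and must return
#' the gradient with respect to the parameters; when absent, gradients are
#' taken by central finite differences (adequate for small parameter
#' counts). Custom maps are never gauge-fixed automatically: their gauge
#' freedoms depend on the model's structure and are the user's
#' responsibility.
#'
#' @slot phiFun function(params, prepared) -> numeric phi per sequence.
#' @slot gradFun function(params, prepared, dphi) -> gradient vector, or
#'   empty list for numeric differentiation.
#' @slot prepare function(sequences, alphabet) -> prepared object.
#' @slot params named numeric vector of current parameter values.
#' @export
setClass("CustomGPMap", contains = "GPMap",
  representation(phiFun = "function", gradFun = "list",
                 prepare = "function", params = "numeric"))

#' Construct a custom G-P map
#'
#' @param L sequence length.
#' @param alphabet an \linkS4class{Alphabet}.
#' @param phiFun function(params, prepared) returning one finite latent
#'   phenotype per sequence (non-finite values on training data abort the
#'   fit with a diagnostic).
#' @param params named numeric vector of initial parameter values.
#' @param gradFun optional analytic gradient, see
#'   \linkS4class{CustomGPMap}.
#' @param prepare optional preprocessing function(sequences, alphabet).
#' @return A \linkS4class{CustomGPMap}.
#' @examples
#' # wrap a one-parameter map: phi = theta * (number of A's)
#' cm <- customGPMap(4, builtinAlphabet("dna"),
#'   phiFun = function(p, seqs) p[["w"]] *
#'     vapply(strsplit(seqs, ""), function(s) sum(s == "A"), 0),
#'   params = c(w = 1))
#' phi(cm, c("AAAA", "ACGT"))
#' @export
customGPMap <- function(L, alphabet, phiFun, params, gradFun = NULL,
                        prepare = NULL) {
  if (is.null(names(params))) names(params) <- paste0("p", seq_along(params))
  new("CustomGPMap", L = as.integer(L), nchars = alphabetSize(alphabet),
      alphabet = alphabet, phiFun = phiFun,
      gradFun = if (is.null(gradFun)) list() else list(gradFun),
      prepare = if (is.null(prepare)) function(sequences, alphabet) sequences
                else prepare,
      params = params)
}

#' @rdname phi
#' @export
setMethod("phi", "CustomGPMap", function(map, sequences) {
  prepared <- map@prepare(toupper(sequences), map@alphabet)
  v <- map@phiFun(map@params, prepared)
  if (length(v) != length(sequences))
    stop("custom phiFun returned ", length(v), " values for ",
         length(sequences), " sequences")
  v
})

#' @rdname nParams
#' @export
setMethod("nParams", "CustomGPMap", function(map) length(map@params))

setMethod("show", "CustomGPMap", function(object) {
  cat("custom G-P map: L =", object@L, ",", length(object@params),
      "parameters (", paste(utils::head(names(object@params), 6),
                            collapse = ", "),
      if (length(object@params) > 6) ", ..." else "", ")\n")
})

# gradient of sum_n dphi_n * phi_n(params) wrt params
.custom_grad <- function(map, prepared, params, dphi, h = 1e-6) {
  if (length(map@gradFun)) return(map@gradFun[[1]](params, prepared, dphi))
  g <- numeric(length(params))
  for (j in seq_along(params)) {
    hp <- params; hp[j] <- hp[j] + h
    hm <- params; hm[j] <- hm[j] - h
    g[j] <- sum(dphi * (map@phiFun(hp, prepared) -
                        map@phiFun(hm, prepared))) / (2 * h)
  }
  g
}
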