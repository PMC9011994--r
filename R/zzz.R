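#' @useDynLib latentmave, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd var cov mad median setNames rnorm runif rbeta
#'   rcauchy rmultinom qnorm qbeta qcauchy pnorm pbeta pcauchy dnorm
#'   dcauchy
#' @importFrom utils head read.table write.table
NULL
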