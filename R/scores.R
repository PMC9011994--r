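#' Log2 enrichment scores from read counts
#'
#' Converts selection-experiment read counts into log enrichment
#' measurements relative to wildtype, with +1 pseudocounts guarding zeros:
#' \deqn{y = \log_2 \frac{(c^{out}+1)/(c^{out}_{WT}+1)}
#'                       {(c^{in}+1)/(c^{in}_{WT}+1)}.}
#'
#' @param cIn,cOut nonnegative integer read counts for each variant in the
#'   input (pre-selection) and output (post-selection) samples; vectorized.
#' @param cWtIn,cWtOut scalar wildtype reference counts.
#' @return Numeric vector of log2 enrichment scores.
#' @examples
#' log2Enrichment(3, 7, 3, 3)  # = 1
#' @export
log2Enrichment <- function(cIn, cOut, cWtIn, cWtOut) {
  .check_counts(c(cIn, cOut, cWtIn, cWtOut))
  log2(((cOut + 1) / (cWtOut + 1)) / ((cIn + 1) / (cWtIn + 1)))
}

#' Log10 PSI scores from barcode counts
#'
#' Converts splicing-assay barcode counts into percent-spliced-in (PSI)
#' measurements on a log10 scale, relative to a consensus splice site:
#' \deqn{y = \log_{10}\left[100 \times \frac{(c^{inc}+1)/(c^{inc}_{CONS}+1)}
#'                       {(c^{tot}+1)/(c^{tot}_{CONS}+1)}\right],}
#' with \eqn{PSI = 10^y} (so the consensus itself scores PSI = 100).
#'
#' @param cInc,cTot inclusion-isoform and total-mRNA barcode counts per
#'   variant; vectorized.
#' @param cConsInc,cConsTot scalar consensus-sequence counts.
#' @return A list with components \code{y} (log10 scale) and \code{psi}
#'   (percent).
#' @examples
#' log10Psi(0, 9, 9, 9)$psi  # = 10
#' @export
log10Psi <- function(cInc, cTot, cConsInc, cConsTot) {
  .check_counts(c(cInc, cTot, cConsInc, cConsTot))
  y <- log10(100 * ((cInc + 1) / (cConsInc + 1)) /
                   ((cTot + 1) / (cConsTot + 1)))
  list(y = y, psi = 10^y)
}

.check_counts <- function(x) {
  if (any(x < 0) || any(x != round(x)))
    stop("read counts must be nonnegative integers")
  invisible(TRUE)
}
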