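#' MAVE dataset
#'
#' Container for the universal input to latent phenotype modeling: a set of
#' fixed-length sequences together with either a continuous measurement per
#' sequence (global epistasis regression), a bin label per read, or a
#' per-sequence vector of read counts across Y bins
#' (measurement-process-agnostic regression). Optional per-measurement
#' standard errors support the empirical noise model.
#'
#' @slot sequences character vector of equal-length sequences.
#' @slot y numeric measurements (GE mode; length 0 otherwise).
#' @slot bins integer bin labels in 0..Y-1, one per read (MPA pair mode).
#' @slot counts M x Y nonnegative integer matrix of per-bin counts
#'   (MPA count mode).
#' @slot se optional per-measurement standard errors (> 0), GE mode only.
#' @slot alphabet the \linkS4class{Alphabet} the sequences are written in.
#'
#' @export
setClass("MaveDataset",
  representation(sequences = "character", y = "numeric", bins = "integer",
                 counts = "matrix", se = "numeric", alphabet = "Alphabet"))

setValidity("MaveDataset", function(object) {
  n <- length(object@sequences)
  if (n < 1L) return("dataset needs at least one sequence")
  idx <- tryCatch(.seq_to_idx(object@sequences, object@alphabet),
                  error = function(e) conditionMessage(e))
  if (is.character(idx)) return(idx)
  modes <- c(ge = length(object@y) > 0L, bins = length(object@bins) > 0L,
             counts = nrow(object@counts) > 0L)
  if (sum(modes) != 1L)
    return("exactly one of {y, bins, counts} must be populated")
  if (modes["ge"]) {
    if (length(object@y) != n) return("length(y) must match sequences")
    if (!all(is.finite(object@y))) return("y must be finite")
    if (length(object@se) > 0L) {
      if (length(object@se) != n) return("length(se) must match sequences")
      if (!all(object@se > 0)) return("se must be positive")
    }
  } else if (length(object@se) > 0L) {
    return("se is only meaningful with continuous measurements")
  }
  if (modes["bins"]) {
    if (length(object@bins) != n) return("length(bins) must match sequences")
    if (any(object@bins < 0L)) return("bins must be nonnegative integers")
  }
  if (modes["counts"]) {
    cts <- object@counts
    if (nrow(cts) != n) return("nrow(counts) must match sequences")
    if (any(cts < 0) || any(cts != round(cts)))
      return("counts must be nonnegative integers")
    if (any(rowSums(cts) < 1)) return("every counts row needs total >= 1")
  }
  TRUE
})

#' Construct a MAVE dataset
#'
#' @param sequences character vector of equal-length sequences.
#' @param y continuous measurements (GE mode).
#' @param bins integer bin labels per read (MPA pair mode).
#' @param counts M x Y nonnegative integer count matrix (MPA count mode).
#' @param se optional per-measurement standard errors (GE mode).
#' @param alphabet an \linkS4class{Alphabet}; defaults to DNA.
#' @return A \linkS4class{MaveDataset}. Exactly one of \code{y},
#'   \code{bins}, \code{counts} must be given.
#' @examples
#' MaveDataset(c("ACGT", "AAGT"), y = c(0.1, -1.2))
#' @export
MaveDataset <- function(sequences, y = NULL, bins = NULL, counts = NULL,
                        se = NULL, alphabet = builtinAlphabet("dna")) {
  new("MaveDataset",
      sequences = toupper(as.character(sequences)),
      y = if (is.null(y)) numeric(0) else as.numeric(y),
      bins = if (is.null(bins)) integer(0) else as.integer(bins),
      counts = if (is.null(counts)) matrix(0, 0, 0) else as.matrix(counts),
      se = if (is.null(se)) numeric(0) else as.numeric(se),
      alphabet = alphabet)
}

#' @rdname MaveDataset-accessors
#' @name MaveDataset-accessors
#' @title Accessors for MaveDataset
#' @param x a \linkS4class{MaveDataset}.
#' @param i index vector for subsetting observations.
#' @param j,drop,... ignored.
#' @return \code{sequences()}: the sequences; \code{measurements()}: the
#'   continuous measurements; \code{binCounts()}: the count matrix;
#'   \code{datasetMode()}: one of \code{"ge"}, \code{"mpa_bins"},
#'   \code{"mpa_counts"}; \code{nObs()}: the number of rows.
NULL

#' @rdname MaveDataset-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("sequences", "MaveDataset", function(x) x@sequences)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("measurements", "MaveDataset", function(x) x@y)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("binCounts", "MaveDataset", function(x) x@counts)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("binLabels", "MaveDataset", function(x) x@bins)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("measurementSE", function(x) standardGeneric("measurementSE"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("measurementSE", "MaveDataset", function(x) x@se)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("datasetAlphabet", function(x) standardGeneric("datasetAlphabet"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("datasetAlphabet", "MaveDataset", function(x) x@alphabet)

#' @rdname MaveDataset-accessors
#' @export
setGeneric("datasetMode", function(x) standardGeneric("datasetMode"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("datasetMode", "MaveDataset", function(x) {
  if (length(x@y) > 0L) "ge"
  else if (length(x@bins) > 0L) "mpa_bins"
  else "mpa_counts"
})

#' @rdname MaveDataset-accessors
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname MaveDataset-accessors
#' @export
setMethod("nObs", "MaveDataset", function(x) length(x@sequences))

#' @rdname MaveDataset-accessors
#' @export
setMethod("[", "MaveDataset", function(x, i, j, ..., drop = FALSE) {
  new("MaveDataset",
      sequences = x@sequences[i],
      y = if (length(x@y)) x@y[i] else numeric(0),
      bins = if (length(x@bins)) x@bins[i] else integer(0),
      counts = if (nrow(x@counts)) x@counts[i, , drop = FALSE]
               else matrix(0, 0, 0),
      se = if (length(x@se)) x@se[i] else numeric(0),
      alphabet = x@alphabet)
})

setMethod("show", "MaveDataset", function(object) {
  cat("MaveDataset:", nObs(object), "observations, L =",
      nchar(object@sequences[1]), "| mode:", datasetMode(object),
      "| alphabet:", object@alphabet@name, "\n")
  if (datasetMode(object) == "mpa_counts")
    cat("  Y =", ncol(object@counts), "bins, total reads:",
        sum(object@counts), "\n")
})

#' Convert between per-read bin labels and per-sequence count matrices
#'
#' \code{binsToCounts} aggregates a pair-mode dataset (one bin label per
#' read) into one row per unique sequence with a Y-column count matrix;
#' \code{countsToBins} performs the inverse expansion (reproducing the reads
#' up to ordering). Likelihoods computed on the two representations agree
#' exactly.
#'
#' @param dataset a \linkS4class{MaveDataset} in the appropriate MPA mode.
#' @param Y number of bins; defaults to \code{max(bins) + 1}.
#' @return A \linkS4class{MaveDataset} in the other MPA mode.
#' @export
binsToCounts <- function(dataset, Y = NULL) {
  stopifnot(datasetMode(dataset) == "mpa_bins")
  bins <- dataset@bins
  if (is.null(Y)) Y <- max(bins) + 1L
  if (any(bins >= Y)) stop("bin label exceeds Y - 1")
  seqs <- unique(dataset@sequences)
  tab <- table(factor(dataset@sequences, levels = seqs),
               factor(bins, levels = 0:(Y - 1L)))
  cts <- matrix(as.integer(tab), nrow = length(seqs))
  colnames(cts) <- paste0("ct_", 0:(Y - 1L))
  MaveDataset(seqs, counts = cts, alphabet = dataset@alphabet)
}

#' @rdname binsToCounts
#' @export
countsToBins <- function(dataset) {
  stopifnot(datasetMode(dataset) == "mpa_counts")
  cts <- dataset@counts
  Y <- ncol(cts)
  seqs <- rep(rep(dataset@sequences, Y), as.vector(cts))
  bins <- rep(rep(0:(Y - 1L), each = nrow(cts)), as.vector(cts))
  MaveDataset(seqs, bins = bins, alphabet = dataset@alphabet)
}

#' Filter rows by a minimum count
#'
#' Retains rows whose count in the named column meets a threshold (e.g.
#' keeping only variants with input-sample read count >= 10 before score
#' computation). Order is preserved and the operation is idempotent; a
#' message reports retained/total.
#'
#' @param x a data.frame with a count column, or a count-mode
#'   \linkS4class{MaveDataset} (where \code{column} may be \code{"total"}
#'   for row sums or a bin column name such as \code{"ct_0"}).
#' @param column name of the count column.
#' @param threshold minimum count to retain a row.
#' @return The filtered object, same class as the input.
#' @export
filterByMinCount <- function(x, column, threshold) {
  if (is(x, "MaveDataset")) {
    stopifnot(datasetMode(x) == "mpa_counts")
    cts <- x@counts
    vals <- if (identical(column, "total")) rowSums(cts)
            else if (column %in% colnames(cts)) cts[, column]
            else stop("count column '", column, "' not found")
    keep <- vals >= threshold
    message("filterByMinCount: retained ", sum(keep), "/", length(keep))
    return(x[which(keep)])
  }
  if (!column %in% names(x)) stop("count column '", column, "' not found")
  keep <- x[[column]] >= threshold
  message("filterByMinCount: retained ", sum(keep), "/", length(keep))
  x[keep, , drop = FALSE]
}

#' Read / write MAVE datasets as TSV
#'
#' The on-disk layout has a header and a \code{seq} column, plus either
#' \code{y} (and optional \code{dy} for per-measurement standard errors),
#' or \code{bin}, or \code{ct_0 .. ct_\{Y-1\}}. Write-then-read is the
#' identity on values.
#'
#' @param path file path.
#' @param alphabet alphabet for the sequences (default DNA).
#' @param sep field separator (tab default; use "," for CSV).
#' @return \code{readMaveDataset}: a \linkS4class{MaveDataset}.
#' @export
readMaveDataset <- function(path, alphabet = builtinAlphabet("dna"),
                            sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (!"seq" %in% names(df)) stop("missing 'seq' column")
  ct_cols <- grep("^ct_[0-9]+$", names(df), value = TRUE)
  if ("y" %in% names(df)) {
    MaveDataset(df$seq, y = df$y,
                se = if ("dy" %in% names(df)) df$dy else NULL,
                alphabet = alphabet)
  } else if ("bin" %in% names(df)) {
    b <- df$bin
    if (any(b != round(b))) stop("non-integer bin labels")
    MaveDataset(df$seq, bins = b, alphabet = alphabet)
  } else if (length(ct_cols) >= 2L) {
    ct_cols <- paste0("ct_", 0:(length(ct_cols) - 1L))
    cts <- as.matrix(df[, ct_cols])
    if (any(cts != round(cts))) stop("non-integer counts")
    MaveDataset(df$seq, counts = cts, alphabet = alphabet)
  } else stop("need a 'y', 'bin', or 'ct_0..ct_{Y-1}' column set")
}

#' @rdname readMaveDataset
#' @param dataset a \linkS4class{MaveDataset} to write.
#' @export
writeMaveDataset <- function(dataset, path, sep = "\t") {
  df <- switch(datasetMode(dataset),
    ge = {
      d <- data.frame(seq = dataset@sequences, y = dataset@y)
      if (length(dataset@se)) d$dy <- dataset@se
      d
    },
    mpa_bins = data.frame(seq = dataset@sequences, bin = dataset@bins),
    mpa_counts = {
      d <- data.frame(seq = dataset@sequences)
      cts <- dataset@counts
      colnames(cts) <- paste0("ct_", 0:(ncol(cts) - 1L))
      cbind(d, as.data.frame(cts))
    })
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
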