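#' @import methods
NULL

#' Sequence alphabet
#'
#' An ordered set of C >= 2 distinct single characters over which
#' fixed-length sequences are defined. Built-in alphabets are provided for
#' DNA, RNA and protein (with or without the stop symbol \code{*}); custom
#' alphabets are supported via \code{Alphabet()}.
#'
#' @slot name identifier for the alphabet.
#' @slot characters ordered character vector of distinct single characters.
#'
#' @export
setClass("Alphabet",
  representation(name = "character", characters = "character"))

setValidity("Alphabet", function(object) {
  ch <- object@characters
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(ch) < 2L) return("alphabet needs at least 2 characters")
  if (any(nchar(ch) != 1L)) return("alphabet characters must be single characters")
  if (anyDuplicated(ch)) return("alphabet characters must be unique")
  TRUE
})

#' Construct an alphabet
#'
#' @param characters character vector of distinct single characters (or one
#'   string, which is split into characters).
#' @param name identifier for the alphabet.
#' @return An \linkS4class{Alphabet} object.
#' @examples
#' Alphabet("ACGT", name = "dna")
#' @export
Alphabet <- function(characters, name = "custom") {
  if (length(characters) == 1L && nchar(characters) > 1L)
    characters <- strsplit(characters, "")[[1]]
  new("Alphabet", name = name, characters = as.character(characters))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Built-in alphabets
#'
#' @param name one of \code{"dna"}, \code{"rna"}, \code{"protein"},
#'   \code{"protein*"} (20 amino acids plus the stop symbol \code{*}).
#' @return An \linkS4class{Alphabet}.
#' @examples
#' alphabetSize(builtinAlphabet("protein*"))
#' @export
builtinAlphabet <- function(name = c("dna", "rna", "protein", "protein*")) {
  name <- match.arg(name)
  switch(name,
    "dna"      = Alphabet(c("A", "C", "G", "T"), "dna"),
    "rna"      = Alphabet(c("A", "C", "G", "U"), "rna"),
    "protein"  = Alphabet(AA20, "protein"),
    "protein*" = Alphabet(c(AA20, "*"), "protein*"))
}

#' @describeIn builtinAlphabet Number of characters C in an alphabet.
#' @param alphabet an \linkS4class{Alphabet}.
#' @export
alphabetSize <- function(alphabet) length(alphabet@characters)

#' @describeIn builtinAlphabet The ordered characters of an alphabet.
#' @export
alphabetCharacters <- function(alphabet) alphabet@characters

setMethod("show", "Alphabet", function(object) {
  cat("Alphabet '", object@name, "' (C = ", length(object@characters),
      "): ", paste(object@characters, collapse = ""), "\n", sep = "")
})

# Map sequences (character vector) to an integer matrix [n x L] of
# 1-based character indices; errors name the offending position/character.
.seq_to_idx <- function(sequences, alphabet) {
  sequences <- toupper(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    bad <- which(nchar(sequences) != nchar(sequences[1]))[1]
    stop("sequences have unequal lengths; first offending row: ", bad)
  }
  chars <- alphabet@characters
  m <- matrix(match(unlist(strsplit(sequences, ""), use.names = FALSE), chars),
              nrow = length(sequences), ncol = L, byrow = TRUE)
  if (anyNA(m)) {
    ij <- which(is.na(m), arr.ind = TRUE)[1, ]
    ch <- substr(sequences[ij[1]], ij[2], ij[2])
    stop("character '", ch, "' at position ", ij[2] - 1L,
         " of sequence ", ij[1], " is not in alphabet '", alphabet@name, "'")
  }
  m
}
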