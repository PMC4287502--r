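## Small shared helpers. None exported.

#' Reverse-complement character vectors of DNA
#'
#' @param x character vector over A,C,G,T,N (any case handled upstream).
#' @return character vector of the same length.
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
seq_c2t <- function(x) chartr("C", "T", x)

#' @noRd
seq_g2a <- function(x) chartr("G", "A", x)

#' Reverse a vector of strings (used to flip quality strings)
#' @noRd
str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Phred+33 decoding of one quality string
#' @noRd
phred_of <- function(qual) as.integer(utf8ToInt(qual)) - 33L

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a consistent prefix
#' @noRd
abort_ma <- function(...) stop(..., call. = FALSE)
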