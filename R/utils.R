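#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported percentages so that
#' e.g. 0.285 prints as 0.29. Base R's `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

DNA_BASES <- c("A", "C", "G", "T")

RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus")

#' Per-sequence GC fraction
#'
#' @param x character vector of DNA sequences (or a `DNAStringSet`).
#' @return numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(x, "GC", as.prob = TRUE))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## single place to stop() with consistent class, so callers can test errors
mc_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
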