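`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

is_dna <- function(x) !grepl("[^ACGTN]", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
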