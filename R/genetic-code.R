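#' The standard genetic code
#'
#' Returns the standard (NCBI table 1) genetic code as a named character
#' vector mapping each of the 64 codons (DNA alphabet) to a one-letter
#' amino-acid code, with `"*"` for the three stop codons (TAA, TAG, TGA).
#'
#' @return named character vector of length 64.
#' @examples
#' genetic_code()[["ATG"]]  # "M"
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  structure(as.character(code), names = names(code))
}

#' Adenosine-containing non-stop codons
#'
#' The set of codons that contain at least one adenosine, excluding the
#' three stop codons. These are the only codons in which an A-to-I(G)
#' edit of a coding position can occur without touching a stop codon;
#' there are exactly 34 of them.
#'
#' @param code genetic code table, as returned by [genetic_code()].
#' @return sorted character vector of codons.
#' @export
adenosine_codons <- function(code = genetic_code()) {
  codons <- names(code)
  sort(codons[grepl("A", codons) & code != "*"])
}

#' Classify the coding consequence of an A-to-G codon edit
#'
#' Compares the reference and edited codon translations under the
#' standard genetic code. Categories follow the usual variant-effect
#' vocabulary: `synonymous` (same amino acid, neither a stop),
#' `nonsynonymous` (different amino acids, neither a stop),
#' `stop_retained` (both stops), `stop_lost` (reference stop, edited
#' codon coding) and `stop_gained` (reference coding, edited codon a
#' stop).
#'
#' @param codon_ref,codon_alt character vectors of reference and edited
#'   codons (3-mers over A/C/G/T). Recycled to a common length.
#' @param code genetic code table.
#' @return character vector of consequence labels.
#' @examples
#' classify_consequence("AAA", "AAG")  # synonymous (Lys -> Lys)
#' classify_consequence("ATA", "ATG")  # nonsynonymous (Ile -> Met)
#' classify_consequence("TAG", "TGG")  # stop_lost
#' @export
classify_consequence <- function(codon_ref, codon_alt, code = genetic_code()) {
  n <- max(length(codon_ref), length(codon_alt))
  codon_ref <- rep_len(toupper(codon_ref), n)
  codon_alt <- rep_len(toupper(codon_alt), n)
  bad <- !codon_ref %in% names(code) | !codon_alt %in% names(code)
  if (any(bad)) {
    stopf("invalid codon(s): %s",
          paste(unique(c(codon_ref[bad], codon_alt[bad])), collapse = ", "))
  }
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  out <- ifelse(
    aa_ref == "*" & aa_alt == "*", "stop_retained",
    ifelse(aa_ref == "*", "stop_lost",
    ifelse(aa_alt == "*", "stop_gained",
    ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous")))
  )
  out
}

#' Enumerate all single A-to-G codon edits
#'
#' Exhaustively enumerates every (codon, position) pair with an adenosine
#' at that position, applies the A-to-G substitution and classifies its
#' consequence. There are 48 such edits under the standard code (16 codons
#' carry an A at each of the three positions). Used as the analytic
#' ground truth for codon-level statistics and as a test oracle.
#'
#' @param code genetic code table.
#' @return data.frame with columns `codon_ref`, `codon_pos`, `codon_alt`,
#'   `aa_ref`, `aa_alt`, `consequence`, one row per possible edit.
#' @examples
#' tab <- enumerate_edits()
#' nrow(tab)               # 48
#' table(tab$consequence)  # 13 synonymous, 31 nonsynonymous, ...
#' @export
enumerate_edits <- function(code = genetic_code()) {
  codons <- names(code)
  rows <- list()
  for (cod in codons) {
    for (p in 1:3) {
      if (substring(cod, p, p) != "A") next
      alt <- cod
      substring(alt, p, p) <- "G"
      rows[[length(rows) + 1L]] <- data.frame(
        codon_ref = cod, codon_pos = p, codon_alt = alt,
        aa_ref = unname(code[cod]), aa_alt = unname(code[alt]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$consequence <- classify_consequence(out$codon_ref, out$codon_alt, code)
  out[order(out$codon_ref, out$codon_pos), , drop = FALSE]
}
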