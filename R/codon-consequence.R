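#' Canonical transcript per gene
#'
#' Codon-level statistics count each edited codon once. To avoid double
#' counting across isoforms, one transcript per gene is used: the one
#' with the longest complete CDS, ties broken by lexicographically
#' smallest transcript id.
#'
#' @param models list of [transcript_model()] objects.
#' @return character vector of canonical transcript ids.
#' @export
canonical_transcripts <- function(models) {
  coding <- Filter(function(t) t$cds_complete, models)
  if (!length(coding)) return(character(0))
  df <- data.frame(
    transcript_id = vapply(coding, `[[`, character(1), "transcript_id"),
    gene_id = vapply(coding, `[[`, character(1), "gene_id"),
    cds_length = vapply(coding, `[[`, integer(1), "cds_length"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id, -df$cds_length, df$transcript_id), ]
  df$transcript_id[!duplicated(df$gene_id)]
}

genomic_to_cds <- function(t, gpos) map_to_spliced(t$cds, t$strand, gpos)

mito_contigs <- c("MT", "chrM", "chrMT", "M")

#' Codon context of a CDS editing site
#'
#' Assembles the codon containing an edited CDS position from the
#' spliced CDS sequence, so codons spanning exon junctions are handled
#' correctly, and classifies the consequence of the A-to-G edit.
#'
#' @param t the host [transcript_model()] (must have a complete CDS).
#' @param gpos 1-based genomic position of the site (must lie in the
#'   CDS of `t`).
#' @param ref reference sequences from [read_fasta()].
#' @param code genetic code table.
#' @return list with `codon_ref`, `codon_alt`, `codon_pos` (1-3, 3 is
#'   the wobble position), `aa_ref`, `aa_alt`, `consequence`, and
#'   `cds_pos` (1-based position within the spliced CDS); or `NULL`
#'   when the transcript is excluded from codon analyses (incomplete
#'   CDS, or an N base in the codon).
#' @export
codon_context <- function(t, gpos, ref, code = genetic_code()) {
  off <- genomic_to_cds(t, gpos)
  if (is.na(off)) stopf("position %d is not in the CDS of '%s'", gpos, t$transcript_id)
  if (!t$cds_complete) return(NULL)
  cds_seq <- cds_sequence(t, ref)
  codon_idx <- (off - 1L) %/% 3L
  codon_pos <- (off - 1L) %% 3L + 1L
  codon_ref <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  if (grepl("N", codon_ref)) return(NULL)
  if (substring(codon_ref, codon_pos, codon_pos) != "A") {
    stopf("internal consistency error: CDS base at %s:%d (%s, CDS pos %d) is '%s', expected 'A'",
          t$contig, gpos, t$transcript_id, off,
          substring(codon_ref, codon_pos, codon_pos))
  }
  codon_alt <- codon_ref
  substring(codon_alt, codon_pos, codon_pos) <- "G"
  list(
    codon_ref = codon_ref, codon_alt = codon_alt, codon_pos = codon_pos,
    aa_ref = unname(code[codon_ref]), aa_alt = unname(code[codon_alt]),
    consequence = classify_consequence(codon_ref, codon_alt, code),
    cds_pos = off
  )
}

#' Annotate CDS editing sites with codon context and consequence
#'
#' Maps every CDS site in an `inosine_sites` table to its codon context
#' (see [codon_context()]). By default, only the canonical transcript
#' of each gene is used (`isoform = "canonical"`), so each edited codon
#' is counted once per gene; `isoform = "all"` emits one row per
#' qualifying isoform. Transcripts with incomplete CDS are excluded;
#' mitochondrial transcripts (contigs MT/chrM) are excluded with a
#' warning because they use a different genetic code.
#'
#' @param sites an `inosine_sites` data.frame ([call_inosine_sites()]).
#' @param models list of [transcript_model()] objects.
#' @param ref reference sequences from [read_fasta()].
#' @param isoform `"canonical"` (default) or `"all"`.
#' @param code genetic code table.
#' @return data.frame with the site key columns plus `codon_ref`,
#'   `codon_alt`, `codon_pos`, `aa_ref`, `aa_alt`, `consequence`,
#'   `efficiency`, `ad_ref`, `ad_alt`.
#' @export
annotate_codons <- function(sites, models, ref,
                            isoform = c("canonical", "all"),
                            code = genetic_code()) {
  isoform <- match.arg(isoform)
  cds_sites <- sites[sites$region == "cds", , drop = FALSE]
  if (any(cds_sites$contig %in% mito_contigs)) {
    warnf("mitochondrial sites excluded from codon analyses")
    cds_sites <- cds_sites[!cds_sites$contig %in% mito_contigs, , drop = FALSE]
  }
  if (isoform == "canonical") {
    keep_tx <- canonical_transcripts(models)
    cds_sites <- cds_sites[cds_sites$transcript_id %in% keep_tx, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(cds_sites))) {
    s <- cds_sites[i, ]
    t <- models[[s$transcript_id]]
    if (is.null(t) || !t$cds_complete) next
    ctx <- codon_context(t, s$gpos, ref, code)
    if (is.null(ctx)) next
    rows[[length(rows) + 1L]] <- cbind(
      s[, c("contig", "gpos", "transcript_id", "transcript_pos",
            "ad_ref", "ad_alt", "efficiency"), drop = FALSE],
      data.frame(cds_pos = ctx$cds_pos, codon_ref = ctx$codon_ref,
                 codon_alt = ctx$codon_alt, codon_pos = ctx$codon_pos,
                 aa_ref = ctx$aa_ref, aa_alt = ctx$aa_alt,
                 consequence = ctx$consequence, stringsAsFactors = FALSE)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(), gpos = integer(), transcript_id = character(),
    transcript_pos = integer(), ad_ref = integer(), ad_alt = integer(),
    efficiency = numeric(), cds_pos = integer(), codon_ref = character(),
    codon_alt = character(), codon_pos = integer(), aa_ref = character(),
    aa_alt = character(), consequence = character(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
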