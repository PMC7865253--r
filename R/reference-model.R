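#' Read a reference FASTA
#'
#' Loads a FASTA file into a named character vector of uppercase DNA
#' sequences, one element per contig. Lowercase (soft-masked) bases are
#' uppercased. Only the DNA alphabet A/C/G/T/N is accepted; anything
#' else (e.g. RNA `U`, IUPAC ambiguity codes) is a format error.
#'
#' @param path path to a FASTA file.
#' @return named character vector (contig name -> sequence). An empty
#'   file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  out <- toupper(as.character(seqs))
  bad <- which(!is_dna(out))
  if (length(bad)) {
    # locate the first offending line for the error message
    lines <- readLines(path, warn = FALSE)
    ln <- which(!startsWith(lines, ">") & !is_dna(toupper(lines)))[1]
    stopf("non-DNA characters in FASTA '%s' (record '%s'%s)",
          path, names(out)[bad[1]],
          if (!is.na(ln)) sprintf(", line %d", ln) else "")
  }
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

sort_intervals <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m)) m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Construct a transcript model
#'
#' A transcript model holds the exon and CDS structure of one transcript
#' on one contig, in 1-based closed genomic coordinates, together with
#' derived UTR intervals. Exons must be non-overlapping; every CDS
#' interval must be contained in an exon. Protein-coding transcripts
#' whose total CDS length is not a positive multiple of 3 are retained
#' (for region annotation) but flagged incomplete and excluded from
#' codon-level analyses.
#'
#' @param transcript_id,gene_id,contig identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix/data.frame of genomic start/end.
#' @param cds optional two-column matrix/data.frame of CDS intervals.
#' @param biotype transcript biotype; defaults to `"protein_coding"`
#'   when a CDS is present, `"misc_RNA"` otherwise.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exons, cds = NULL, biotype = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- sort_intervals(exons)
  if (!nrow(exons)) stopf("transcript '%s' has no exons", transcript_id)
  if (any(exons[, 2] < exons[, 1])) {
    stopf("transcript '%s': exon end < start", transcript_id)
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stopf("transcript '%s': overlapping exons", transcript_id)
  }
  if (is.null(cds) || NROW(cds) == 0) {
    cds <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  } else {
    cds <- sort_intervals(cds)
    in_exon <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(in_exon)) {
      stopf("transcript '%s': CDS interval outside exons", transcript_id)
    }
  }
  cds_len <- if (nrow(cds)) sum(cds[, 2] - cds[, 1] + 1L) else 0L
  has_cds <- cds_len > 0L
  # UTRs: exonic minus CDS, assigned 5'/3' by genomic side and strand
  utr5 <- utr3 <- matrix(integer(0), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  if (has_cds) {
    ex <- IRanges::IRanges(exons[, 1], exons[, 2])
    cd <- IRanges::IRanges(cds[, 1], cds[, 2])
    non_cds <- IRanges::setdiff(ex, cd)
    if (length(non_cds)) {
      m <- cbind(start = IRanges::start(non_cds), end = IRanges::end(non_cds))
      before <- m[, 2] < min(cds[, 1])
      after <- m[, 1] > max(cds[, 2])
      left <- m[before, , drop = FALSE]
      right <- m[after, , drop = FALSE]
      if (strand == "+") { utr5 <- left;  utr3 <- right }
      else               { utr5 <- right; utr3 <- left }
    }
  }
  structure(
    list(
      transcript_id = as.character(transcript_id),
      gene_id = as.character(gene_id),
      contig = as.character(contig),
      strand = strand,
      exons = exons,
      cds = cds,
      utr5 = utr5,
      utr3 = utr3,
      biotype = biotype %||% if (has_cds) "protein_coding" else "misc_RNA",
      cds_length = cds_len,
      cds_complete = has_cds && cds_len %% 3L == 0L,
      span = c(min(exons[, 1]), max(exons[, 2]))
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s)\n", x$transcript_id, x$gene_id))
  cat(sprintf("  %s:%d-%d (%s), %d exon(s), CDS %d nt%s, biotype %s\n",
              x$contig, x$span[1], x$span[2], x$strand, nrow(x$exons),
              x$cds_length,
              if (x$cds_length && !x$cds_complete) " [incomplete]" else "",
              x$biotype))
  invisible(x)
}

#' Read gene models from GFF3 or GTF
#'
#' Parses transcript structures (mRNA/transcript, exon and CDS features)
#' into a list of [transcript_model()] objects. GFF3 features are linked
#' via `ID`/`Parent` attributes; GTF via `transcript_id`/`gene_id`.
#' Transcripts whose CDS falls outside their exons are rejected with a
#' warning; exon/CDS features whose parent transcript is absent are
#' skipped with a warning.
#'
#' @param path path to a GFF3 or GTF file.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return named list of `transcript_model` objects (names are
#'   transcript ids).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene model file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)

  if (format == "gff3") {
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
    parent <- if ("Parent" %in% names(mc)) {
      vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
    } else rep(NA_character_, length(gr))
    tx_idx <- which(type %in% c("mRNA", "transcript"))
    tx_ids <- id[tx_idx]
    child_tx <- parent
  } else {
    tx_ids_all <- as.character(mc$transcript_id)
    tx_idx <- which(type %in% c("transcript", "mRNA"))
    if (!length(tx_idx)) {
      # GTFs often lack explicit transcript lines; derive from exons
      tx_ids <- unique(tx_ids_all[type == "exon"])
      tx_idx <- match(tx_ids, tx_ids_all)
    } else {
      tx_ids <- tx_ids_all[tx_idx]
    }
    child_tx <- tx_ids_all
  }

  models <- list()
  child_types <- c("exon", "CDS")
  is_child <- type %in% child_types
  orphan <- is_child & !(child_tx %in% tx_ids)
  if (any(orphan)) {
    warnf("%d exon/CDS feature(s) with no parent transcript skipped", sum(orphan))
  }
  for (k in seq_along(tx_ids)) {
    tid <- tx_ids[k]
    i <- tx_idx[k]
    rows <- which(is_child & child_tx == tid)
    ex <- rows[type[rows] == "exon"]
    cd <- rows[type[rows] == "CDS"]
    if (!length(ex)) {
      warnf("transcript '%s' has no exons; skipped", tid)
      next
    }
    gene <- if (format == "gff3") {
      gid <- parent[i]
      if (is.na(gid) && "gene_id" %in% names(mc)) gid <- as.character(mc$gene_id[i])
      gid %||% NA_character_
    } else {
      as.character(mc$gene_id[i])
    }
    bt <- NULL
    for (f in c("biotype", "transcript_biotype", "gene_biotype")) {
      if (f %in% names(mc) && !is.na(mc[[f]][i])) { bt <- as.character(mc[[f]][i]); break }
    }
    m <- tryCatch(
      transcript_model(
        transcript_id = tid, gene_id = gene,
        contig = contig[i], strand = strand[i],
        exons = cbind(starts[ex], ends[ex]),
        cds = if (length(cd)) cbind(starts[cd], ends[cd]) else NULL,
        biotype = bt
      ),
      error = function(e) {
        warnf("transcript '%s' rejected: %s", tid, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(m)) models[[tid]] <- m
  }
  models
}

exon_order <- function(t) {
  n <- nrow(t$exons)
  if (t$strand == "+") seq_len(n) else rev(seq_len(n))
}

extract_interval <- function(ref_seq, start, end) substring(ref_seq, start, end)

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a transcript in transcription
#' order, reverse-complementing for minus-strand transcripts, yielding
#' the mature (sense) transcript sequence.
#'
#' @param t a [transcript_model()].
#' @param ref named character vector from [read_fasta()], or a single
#'   contig sequence.
#' @return character scalar, the spliced sense sequence.
#' @export
spliced_sequence <- function(t, ref) {
  seq <- if (length(ref) > 1 || !is.null(names(ref))) ref[[t$contig]] else ref
  if (is.null(seq) || is.na(seq)) stopf("contig '%s' not in reference", t$contig)
  if (t$span[2] > nchar(seq)) {
    stopf("transcript '%s' exceeds contig '%s' bounds (%d > %d)",
          t$transcript_id, t$contig, t$span[2], nchar(seq))
  }
  chunks <- substring(seq, t$exons[, 1], t$exons[, 2])
  out <- paste(chunks, collapse = "")
  if (t$strand == "-") out <- revcomp(out)
  out
}

#' Spliced CDS sequence of a transcript
#'
#' @inheritParams spliced_sequence
#' @return character scalar; `""` for transcripts without CDS.
#' @export
cds_sequence <- function(t, ref) {
  if (!nrow(t$cds)) return("")
  tt <- t
  tt$exons <- t$cds
  tt$span <- c(min(t$cds[, 1]), max(t$cds[, 2]))
  spliced_sequence(tt, ref)
}

map_to_spliced <- function(intervals, strand, gpos) {
  # 1-based position within the spliced concatenation of `intervals`
  # (transcription order), or NA if gpos is not inside any interval.
  widths <- intervals[, 2] - intervals[, 1] + 1L
  n <- nrow(intervals)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- 0L
  for (i in ord) {
    if (gpos >= intervals[i, 1] && gpos <= intervals[i, 2]) {
      off <- if (strand == "+") gpos - intervals[i, 1] + 1L
             else intervals[i, 2] - gpos + 1L
      return(unname(cum + off))
    }
    cum <- cum + widths[i]
  }
  NA_integer_
}

#' Map a genomic position to transcript coordinates
#'
#' @param t a [transcript_model()].
#' @param gpos 1-based genomic position.
#' @return list with `pos` (1-based spliced transcript coordinate, or
#'   `NA`) and `status` (`"exonic"`, `"intron"` or `"outside"`).
#' @export
genomic_to_transcript <- function(t, gpos) {
  gpos <- as.integer(gpos)
  stopifnot(length(gpos) == 1, gpos > 0)
  pos <- map_to_spliced(t$exons, t$strand, gpos)
  if (!is.na(pos)) return(list(pos = pos, status = "exonic"))
  if (gpos >= t$span[1] && gpos <= t$span[2]) {
    return(list(pos = NA_integer_, status = "intron"))
  }
  list(pos = NA_integer_, status = "outside")
}

#' Map a transcript coordinate back to the genome
#'
#' Inverse of [genomic_to_transcript()] for exonic positions.
#'
#' @param t a [transcript_model()].
#' @param tpos 1-based spliced transcript coordinate.
#' @return 1-based genomic position.
#' @export
transcript_to_genomic <- function(t, tpos) {
  tpos <- as.integer(tpos)
  total <- sum(t$exons[, 2] - t$exons[, 1] + 1L)
  if (tpos < 1L || tpos > total) {
    stopf("transcript position %d outside transcript '%s' (length %d)",
          tpos, t$transcript_id, total)
  }
  widths <- t$exons[, 2] - t$exons[, 1] + 1L
  cum <- 0L
  for (i in exon_order(t)) {
    if (tpos <= cum + widths[i]) {
      off <- tpos - cum
      return(unname(if (t$strand == "+") t$exons[i, 1] + off - 1L
                    else t$exons[i, 2] - off + 1L))
    }
    cum <- cum + widths[i]
  }
  stop("unreachable")
}

in_any <- function(m, gpos) nrow(m) > 0 && any(m[, 1] <= gpos & gpos <= m[, 2])

#' Region of a genomic position within a transcript
#'
#' Classifies a position inside the genomic span of a transcript as
#' `five_prime_utr`, `cds`, `intron`, `three_prime_utr` or, for
#' transcripts without CDS, `noncoding_exon`. Each position receives
#' exactly one label; CDS and UTR intervals are disjoint by
#' construction.
#'
#' @param t a [transcript_model()].
#' @param gpos 1-based genomic position within the transcript span.
#' @return character scalar region label.
#' @export
region_of <- function(t, gpos) {
  gpos <- as.integer(gpos)
  if (gpos < t$span[1] || gpos > t$span[2]) {
    stopf("position %d outside span of transcript '%s'", gpos, t$transcript_id)
  }
  if (in_any(t$cds, gpos)) return("cds")
  if (in_any(t$exons, gpos)) {
    if (!nrow(t$cds)) return("noncoding_exon")
    if (in_any(t$utr5, gpos)) return("five_prime_utr")
    if (in_any(t$utr3, gpos)) return("three_prime_utr")
    # exonic, CDS present, but not in a UTR interval: can only happen
    # for exotic models; classify by genomic side of the CDS
    before <- gpos < min(t$cds[, 1])
    if (t$strand == "+") return(if (before) "five_prime_utr" else "three_prime_utr")
    return(if (before) "three_prime_utr" else "five_prime_utr")
  }
  "intron"
}

region_levels <- function() {
  c("five_prime_utr", "cds", "intron", "three_prime_utr", "noncoding_exon")
}
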