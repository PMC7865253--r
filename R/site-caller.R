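#' Read biallelic SNVs with allelic depths from a VCF
#'
#' Parses a VCF into a data.frame of single-nucleotide variants with
#' per-allele read depths taken from the `AD` FORMAT field (ref, alt
#' order). Multiallelic records are split into one row per alternate
#' allele; indels are skipped with a warning.
#'
#' @param path path to a VCF (4.x) file.
#' @param sample sample name; may be omitted for single-sample VCFs.
#' @return data.frame with columns `contig`, `gpos`, `ref`, `alt`,
#'   `ad_ref`, `ad_alt`, `sample_id`.
#' @export
read_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (is.null(sample)) {
    if (length(samples) != 1) {
      stopf("VCF has %d samples; specify `sample`", length(samples))
    }
    sample <- samples[1]
  }
  if (!sample %in% samples) {
    stopf("sample '%s' not in VCF (samples: %s)", sample,
          paste(samples, collapse = ", "))
  }
  g <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(g)) stopf("VCF '%s' lacks the AD FORMAT field", path)
  ad <- g$AD[, sample]
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(rr$REF)
  alts <- rr$ALT  # DNAStringSetList
  contigs <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)

  rows <- vector("list", length(rr))
  n_indel <- 0L
  for (i in seq_along(rr)) {
    alt_i <- as.character(alts[[i]])
    ad_i <- ad[[i]]
    if (length(ad_i) == 1 && all(is.na(ad_i))) {
      stopf("record %s at %s:%d has no AD value", ids[i], contigs[i], pos[i])
    }
    keep <- logical(length(alt_i))
    out_i <- list()
    for (j in seq_along(alt_i)) {
      if (nchar(refs[i]) != 1L || nchar(alt_i[j]) != 1L || alt_i[j] %in% c("*", ".")) {
        n_indel <- n_indel + 1L
        next
      }
      out_i[[length(out_i) + 1L]] <- data.frame(
        contig = contigs[i], gpos = pos[i],
        ref = refs[i], alt = alt_i[j],
        ad_ref = as.integer(ad_i[1]), ad_alt = as.integer(ad_i[1 + j]),
        sample_id = sample, stringsAsFactors = FALSE
      )
    }
    if (length(out_i)) rows[[i]] <- do.call(rbind, out_i)
  }
  if (n_indel) warnf("%d non-SNV allele(s) skipped", n_indel)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(contig = character(), gpos = integer(),
                      ref = character(), alt = character(),
                      ad_ref = integer(), ad_alt = integer(),
                      sample_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a known-SNP blacklist
#'
#' Accepts either a VCF (positions of known polymorphisms) or a
#' two-column TSV (`contig`, `pos`), with or without a header line.
#'
#' @param path path to the blacklist file.
#' @return data.frame with columns `contig`, `gpos`.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stopf("blacklist file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "##fileformat=VCF")) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    return(data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
                      gpos = GenomicRanges::start(rr),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "gpos"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.integer(df$gpos[1])))) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  df$gpos <- as.integer(df$gpos)
  rownames(df) <- NULL
  df
}

#' Construct / read a transcript abundance table
#'
#' @param x data.frame with columns `transcript_id` and `tpm`, or a
#'   named numeric vector of TPMs.
#' @param spike_in_id optional id of a spike-in row (e.g. an mCherry
#'   control transcript) used for normalization.
#' @param spike_in_nominal_tpm nominal TPM of the spike-in.
#' @return data.frame of class `abundance_table` with attributes
#'   `spike_in_id` and `spike_in_nominal_tpm`.
#' @export
abundance_table <- function(x, spike_in_id = NULL, spike_in_nominal_tpm = NULL) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(transcript_id = names(x), tpm = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "tpm") %in% names(x)))
  if (any(x$tpm < 0)) stopf("negative TPM values")
  if (!is.null(spike_in_id) && !spike_in_id %in% x$transcript_id) {
    stopf("spike-in '%s' not present in abundance table", spike_in_id)
  }
  structure(
    x[, c("transcript_id", "tpm")],
    spike_in_id = spike_in_id,
    spike_in_nominal_tpm = spike_in_nominal_tpm,
    class = c("abundance_table", "data.frame")
  )
}

#' Read a transcript abundance TSV
#'
#' Expects two tab-separated columns, `transcript_id` and `tpm` (a
#' header line is detected and skipped).
#'
#' @inheritParams abundance_table
#' @param path path to the TSV.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, spike_in_id = NULL, spike_in_nominal_tpm = NULL) {
  if (!file.exists(path)) stopf("abundance file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("transcript_id", "tpm"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$tpm[1])))) {
    df <- df[-1, , drop = FALSE]
  }
  df$tpm <- as.numeric(df$tpm)
  rownames(df) <- NULL
  abundance_table(df, spike_in_id, spike_in_nominal_tpm)
}

#' Normalize an abundance table to its spike-in
#'
#' Rescales every TPM by `nominal / observed` spike-in TPM (so that the
#' spike-in would hit its nominal value exactly), then drops the
#' spike-in row.
#'
#' @param ab an [abundance_table()] with a configured spike-in.
#' @return an `abundance_table` without the spike-in row.
#' @export
normalize_to_spike <- function(ab) {
  sid <- attr(ab, "spike_in_id")
  nominal <- attr(ab, "spike_in_nominal_tpm")
  if (is.null(sid)) stopf("no spike-in configured on this abundance table")
  i <- match(sid, ab$transcript_id)
  if (is.na(i)) stopf("spike-in '%s' absent from abundance table", sid)
  observed <- ab$tpm[i]
  if (observed == 0) stopf("observed spike-in TPM is zero; cannot normalize")
  out <- ab[-i, , drop = FALSE]
  out$tpm <- out$tpm * (nominal / observed)
  rownames(out) <- NULL
  abundance_table(out)
}

#' Remove known SNP positions from a variant set
#'
#' @param sites variant data.frame as from [read_vcf()].
#' @param blacklist data.frame with `contig`, `gpos` (from
#'   [read_blacklist()]), or NULL for no filtering.
#' @return the sites whose (contig, gpos) is not blacklisted, order
#'   preserved.
#' @export
filter_known_snps <- function(sites, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) return(sites)
  key <- paste(sites$contig, sites$gpos)
  bad <- key %in% paste(blacklist$contig, blacklist$gpos)
  sites[!bad, , drop = FALSE]
}

#' Orient variant alleles to the transcript sense strand
#'
#' Variant callers may report alleles in genomic (plus-strand) or sense
#' (transcribed-strand) orientation. Under `dialect = "genomic"`,
#' alleles of variants on minus-strand transcripts are complemented (a
#' genomic T>C becomes a sense A>G); under `dialect = "sense"` alleles
#' pass through unchanged. Only sense A>G pairs are inosine candidates.
#'
#' @param ref,alt single reference/alternate bases as reported.
#' @param strand transcript strand, `"+"` or `"-"`.
#' @param dialect `"sense"` (default) or `"genomic"`.
#' @return list with `ref` and `alt`, sense-oriented.
#' @export
orient_to_sense <- function(ref, alt, strand, dialect = c("sense", "genomic")) {
  dialect <- match.arg(dialect)
  if (dialect == "genomic" && strand == "-") {
    list(ref = complement_base(ref), alt = complement_base(alt))
  } else {
    list(ref = ref, alt = alt)
  }
}

empty_sites <- function() {
  structure(
    data.frame(contig = character(), gpos = integer(),
               transcript_id = character(), transcript_pos = integer(),
               region = character(), ref = character(), alt = character(),
               ad_ref = integer(), ad_alt = integer(),
               efficiency = numeric(), sample_id = character(),
               stringsAsFactors = FALSE),
    class = c("inosine_sites", "data.frame")
  )
}

#' Call inosine (A-to-I) editing sites
#'
#' Applies the editing-site identification rules to a set of RNA-seq
#' variant calls: known-SNP exclusion, overlap with gene models,
#' sense-strand orientation, retention of sense A>G mismatches only,
#' alternate-allele depth above threshold, and host-transcript
#' abundance at or above the TPM threshold. Each passing site is
#' annotated with its transcript, spliced transcript position, region
#' label and editing efficiency `ad_alt / (ad_ref + ad_alt)` (the
#' standard allelic-fraction editing index).
#'
#' A variant overlapping several qualifying transcripts yields one row
#' per transcript; unique-transcript counting happens downstream in
#' [count_modified_transcripts()].
#'
#' @param variants data.frame from [read_vcf()].
#' @param models list of [transcript_model()] objects.
#' @param abundance an [abundance_table()]; if it has a configured
#'   spike-in, TPMs are spike-normalized before thresholding.
#' @param blacklist optional known-SNP positions ([read_blacklist()]).
#' @param dialect allele orientation of the input VCF, `"sense"`
#'   (default) or `"genomic"`; see [orient_to_sense()].
#' @param tpm_min minimum host-transcript TPM (default 1).
#' @param min_ad_alt minimum alternate-allele read depth (default 1,
#'   i.e. AD > 0).
#' @param verbose print per-filter removal counts.
#' @return data.frame of class `inosine_sites`, sorted by (contig,
#'   gpos, transcript_id), with a `filter_tally` attribute recording
#'   how many candidates each filter removed.
#' @export
call_inosine_sites <- function(variants, models, abundance,
                               blacklist = NULL,
                               dialect = c("sense", "genomic"),
                               tpm_min = 1, min_ad_alt = 1,
                               verbose = FALSE) {
  dialect <- match.arg(dialect)
  tally <- c(input = nrow(variants), known_snp = 0L, no_transcript = 0L,
             not_a_to_g = 0L, low_ad = 0L, low_tpm = 0L, kept = 0L)

  kept <- filter_known_snps(variants, blacklist)
  tally["known_snp"] <- nrow(variants) - nrow(kept)

  if (inherits(abundance, "abundance_table") &&
      !is.null(attr(abundance, "spike_in_id"))) {
    abundance <- normalize_to_spike(abundance)
  }
  tpm <- stats::setNames(abundance$tpm, abundance$transcript_id)

  # per-contig transcript index
  by_contig <- split(models, vapply(models, `[[`, character(1), "contig"))

  rows <- list()
  for (i in seq_len(nrow(kept))) {
    v <- kept[i, ]
    tx <- by_contig[[v$contig]]
    hits <- Filter(function(t) v$gpos >= t$span[1] && v$gpos <= t$span[2], tx)
    if (!length(hits)) {
      tally["no_transcript"] <- tally["no_transcript"] + 1L
      next
    }
    for (t in hits) {
      o <- orient_to_sense(v$ref, v$alt, t$strand, dialect)
      if (!(o$ref == "A" && o$alt == "G")) {
        tally["not_a_to_g"] <- tally["not_a_to_g"] + 1L
        next
      }
      if (v$ad_alt < min_ad_alt) {
        tally["low_ad"] <- tally["low_ad"] + 1L
        next
      }
      host_tpm <- tpm[t$transcript_id]
      if (is.na(host_tpm) || host_tpm < tpm_min) {
        tally["low_tpm"] <- tally["low_tpm"] + 1L
        next
      }
      loc <- genomic_to_transcript(t, v$gpos)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = v$contig, gpos = v$gpos,
        transcript_id = t$transcript_id,
        transcript_pos = loc$pos,
        region = region_of(t, v$gpos),
        ref = o$ref, alt = o$alt,
        ad_ref = v$ad_ref, ad_alt = v$ad_alt,
        efficiency = v$ad_alt / (v$ad_ref + v$ad_alt),
        sample_id = v$sample_id,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  out <- out[order(out$contig, out$gpos, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  tally["kept"] <- nrow(out)
  attr(out, "filter_tally") <- tally
  class(out) <- c("inosine_sites", "data.frame")
  if (verbose) {
    message(sprintf(
      "call_inosine_sites: %d variants in; removed %d known SNPs, %d without transcript, %d non A>G, %d low AD, %d low TPM; %d site rows kept",
      tally["input"], tally["known_snp"], tally["no_transcript"],
      tally["not_a_to_g"], tally["low_ad"], tally["low_tpm"], tally["kept"]))
  }
  out
}

#' @export
print.inosine_sites <- function(x, ...) {
  cat(sprintf("<inosine_sites> %d site row(s) on %d transcript(s)\n",
              nrow(x), length(unique(x$transcript_id))))
  if (nrow(x)) {
    print.data.frame(utils::head(x, 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  }
  invisible(x)
}

#' @export
summary.inosine_sites <- function(object, ...) {
  cat(sprintf("Inosine sites: %d rows, %d unique transcripts\n",
              nrow(object), length(unique(object$transcript_id))))
  if (nrow(object)) {
    cat("Region distribution:\n")
    print(region_distribution(object))
    cat(sprintf("Mean editing efficiency: %.3f\n", mean(object$efficiency)))
  }
  tally <- attr(object, "filter_tally")
  if (!is.null(tally)) {
    cat("Filter tally:\n")
    print(tally)
  }
  invisible(object)
}
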