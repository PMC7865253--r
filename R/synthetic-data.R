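#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome generator. Defaults emulate
#' the statistical structure of oocyte total-RNA editing data: per-site
#' editing efficiency centred on 0.5 (Beta(8,8)), editing biased to the
#' codon wobble position (weights 0.2/0.2/0.6), most sites in CDS and
#' 3' UTR, transcript TPMs spanning the TPM >= 1 reporting threshold,
#' a small rate of known-SNP decoys, and an mCherry-style spike-in row
#' in the abundance table.
#'
#' @param seed integer seed; all generator output is deterministic
#'   given the seed.
#' @param n_genes number of genes (one transcript per gene, one contig
#'   per gene).
#' @param exons_per_gene integer range `c(min, max)`.
#' @param utr5_length,utr3_length,intron_length nucleotide ranges.
#' @param cds_codons range of CDS lengths in codons.
#' @param strand_minus_frac probability a gene is on the minus strand.
#' @param n_edit_sites number of planted (non-decoy) editing sites.
#' @param fraction_transcripts_modified fraction of transcripts eligible
#'   to carry edits; the rest stay unmodified, so the modified
#'   proportion of the transcriptome is itself a planted quantity.
#'   Decoy SNPs may fall on any transcript.
#' @param region_mix named weights over `five_prime_utr`, `cds`,
#'   `intron`, `three_prime_utr` for site placement.
#' @param wobble_bias weights for codon positions 1-3 of CDS sites.
#' @param efficiency either `list(dist = "fixed", value = x)` or
#'   `list(dist = "beta", shape1 = a, shape2 = b)`.
#' @param read_depth total read depth per site; `ad_alt ~
#'   Binomial(read_depth, efficiency)`.
#' @param tpm_meanlog,tpm_sdlog log-normal parameters for expressed
#'   transcripts (shifted above 1).
#' @param fraction_below_tpm1 fraction of transcripts drawn below the
#'   TPM = 1 threshold.
#' @param snp_rate SNP decoy rate, as a fraction of `n_edit_sites`;
#'   decoys are emitted in the VCF and listed in the blacklist.
#' @param spike_in `list(id =, nominal_tpm =, observed_factor =)` or
#'   NULL; the emitted abundance row carries
#'   `nominal_tpm * observed_factor`.
#' @param dialect allele orientation written to the VCF: `"sense"`
#'   (A>G always) or `"genomic"` (T>C for minus-strand sites).
#' @param sample_id sample name used in the VCF.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 60L,
                       exons_per_gene = c(1L, 4L),
                       utr5_length = c(30L, 90L),
                       utr3_length = c(60L, 240L),
                       cds_codons = c(60L, 240L),
                       intron_length = c(40L, 120L),
                       strand_minus_frac = 0.5,
                       n_edit_sites = 300L,
                       fraction_transcripts_modified = 0.5,
                       region_mix = c(five_prime_utr = 0.05, cds = 0.60,
                                      intron = 0.05, three_prime_utr = 0.30),
                       wobble_bias = c(0.2, 0.2, 0.6),
                       efficiency = list(dist = "beta", shape1 = 8, shape2 = 8),
                       read_depth = 50L,
                       tpm_meanlog = 1.5,
                       tpm_sdlog = 1.2,
                       fraction_below_tpm1 = 0.25,
                       snp_rate = 0.05,
                       spike_in = list(id = "mCherry", nominal_tpm = 100,
                                       observed_factor = 1),
                       dialect = c("sense", "genomic"),
                       sample_id = "sample1") {
  dialect <- match.arg(dialect)
  stopifnot(
    length(wobble_bias) == 3, all(wobble_bias >= 0), sum(wobble_bias) > 0,
    n_genes >= 1, n_edit_sites >= 0,
    exons_per_gene[1] >= 1, exons_per_gene[2] >= exons_per_gene[1],
    cds_codons[1] >= 2,
    fraction_below_tpm1 >= 0, fraction_below_tpm1 <= 1,
    fraction_transcripts_modified > 0, fraction_transcripts_modified <= 1,
    snp_rate >= 0, snp_rate <= 1, read_depth >= 1
  )
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              cds_codons = as.integer(cds_codons),
              intron_length = as.integer(intron_length),
              strand_minus_frac = strand_minus_frac,
              n_edit_sites = as.integer(n_edit_sites),
              fraction_transcripts_modified = fraction_transcripts_modified,
              region_mix = region_mix, wobble_bias = wobble_bias,
              efficiency = efficiency, read_depth = as.integer(read_depth),
              tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
              fraction_below_tpm1 = fraction_below_tpm1,
              snp_rate = snp_rate, spike_in = spike_in,
              dialect = dialect, sample_id = sample_id)
  class(cfg) <- "sim_config"
  cfg
}

rand_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

PAD <- 20L

#' Generate a synthetic reference and gene models
#'
#' Builds random multi-exon genes with 5' UTR / CDS / intron / 3' UTR
#' structure on both strands, one contig per gene. CDS lengths are
#' multiples of 3 by construction. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `seqs` (named character vector of contigs) and
#'   `models` (named list of [transcript_model()]s).
#' @export
generate_reference <- function(cfg) {
  set.seed(cfg$seed)
  seqs <- character(0)
  models <- list()
  for (i in seq_len(cfg$n_genes)) {
    contig <- sprintf("ctg%03d", i)
    gene_id <- sprintf("gene%03d", i)
    tx_id <- sprintf("tx%03d", i)
    n_ex <- rand_range(cfg$exons_per_gene)
    u5 <- rand_range(cfg$utr5_length)
    u3 <- rand_range(cfg$utr3_length)
    cds_len <- 3L * rand_range(cfg$cds_codons)
    tx_len <- u5 + cds_len + u3
    tx_seq <- rand_dna(tx_len)
    cuts <- if (n_ex > 1) sort(sample(seq_len(tx_len - 1L), n_ex - 1L)) else integer(0)
    bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, tx_len))
    intron_lens <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1L), function(k) rand_range(cfg$intron_length),
             integer(1))
    } else integer(0)
    # assemble plus-strand layout: pad, exon1, intron1, ..., exonN, pad
    pieces <- character(0)
    exon_g <- matrix(integer(0), ncol = 2)
    cursor <- PAD
    pieces <- c(pieces, rand_dna(PAD))
    for (k in seq_len(n_ex)) {
      w <- bounds[k, 2] - bounds[k, 1] + 1L
      exon_g <- rbind(exon_g, c(cursor + 1L, cursor + w))
      pieces <- c(pieces, substring(tx_seq, bounds[k, 1], bounds[k, 2]))
      cursor <- cursor + w
      if (k < n_ex) {
        pieces <- c(pieces, rand_dna(intron_lens[k]))
        cursor <- cursor + intron_lens[k]
      }
    }
    pieces <- c(pieces, rand_dna(PAD))
    contig_seq <- paste(pieces, collapse = "")
    # CDS in transcript coords [u5+1, u5+cds_len] -> genomic intervals
    cds_g <- matrix(integer(0), ncol = 2)
    for (k in seq_len(n_ex)) {
      a <- max(bounds[k, 1], u5 + 1L)
      b <- min(bounds[k, 2], u5 + cds_len)
      if (a <= b) {
        off <- exon_g[k, 1] - bounds[k, 1]
        cds_g <- rbind(cds_g, c(a + off, b + off))
      }
    }
    strand <- if (stats::runif(1) < cfg$strand_minus_frac) "-" else "+"
    if (strand == "-") {
      L <- nchar(contig_seq)
      contig_seq <- revcomp(contig_seq)
      flip <- function(m) {
        if (!nrow(m)) return(m)
        out <- cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
        out[order(out[, 1]), , drop = FALSE]
      }
      exon_g <- flip(exon_g)
      cds_g <- flip(cds_g)
    }
    seqs[contig] <- contig_seq
    models[[tx_id]] <- transcript_model(tx_id, gene_id, contig, strand,
                                        exons = exon_g, cds = cds_g,
                                        biotype = "protein_coding")
  }
  list(seqs = seqs, models = models)
}

# sense-strand candidate positions (genomic) for planting an edit
candidate_positions <- function(t, seqs, region, wobble_bias = NULL) {
  if (region == "intron") {
    n <- nrow(t$exons)
    if (n < 2) return(integer(0))
    gaps <- cbind(t$exons[-n, 2] + 1L, t$exons[-1, 1] - 1L)
    target <- if (t$strand == "+") "A" else "T"
    pos <- integer(0)
    seq <- seqs[[t$contig]]
    for (k in seq_len(nrow(gaps))) {
      sub <- substring(seq, gaps[k, 1], gaps[k, 2])
      hit <- which(strsplit(sub, "")[[1]] == target)
      pos <- c(pos, gaps[k, 1] + hit - 1L)
    }
    return(pos)
  }
  if (region == "cds") {
    if (!t$cds_complete) return(integer(0))
    s <- cds_sequence(t, seqs)
    a <- which(strsplit(s, "")[[1]] == "A")
    if (!length(a)) return(integer(0))
    cpos <- (a - 1L) %% 3L + 1L
    if (!is.null(wobble_bias)) {
      avail <- tabulate(cpos, 3L)
      w <- wobble_bias * (avail > 0)
      if (sum(w) == 0) return(integer(0))
      p <- sample(1:3, 1L, prob = w)
      a <- a[cpos == p]
    }
    return(vapply(a, function(off) cds_offset_to_genomic(t, off), integer(1)))
  }
  # UTRs: transcript-coordinate scan of the spliced sense sequence
  s <- spliced_sequence(t, seqs)
  tx_len <- nchar(s)
  u5w <- if (nrow(t$utr5)) sum(t$utr5[, 2] - t$utr5[, 1] + 1L) else 0L
  u3w <- if (nrow(t$utr3)) sum(t$utr3[, 2] - t$utr3[, 1] + 1L) else 0L
  rng <- if (region == "five_prime_utr") {
    if (u5w == 0) return(integer(0)) else c(1L, u5w)
  } else {
    if (u3w == 0) return(integer(0)) else c(tx_len - u3w + 1L, tx_len)
  }
  bases <- strsplit(substring(s, rng[1], rng[2]), "")[[1]]
  tpos <- rng[1] + which(bases == "A") - 1L
  vapply(tpos, function(p) transcript_to_genomic(t, p), integer(1))
}

cds_offset_to_genomic <- function(t, off) {
  tt <- t
  tt$exons <- t$cds
  transcript_to_genomic(tt, off)
}

draw_efficiency <- function(eff_spec, n) {
  if (eff_spec$dist == "fixed") rep(eff_spec$value, n)
  else stats::rbeta(n, eff_spec$shape1, eff_spec$shape2)
}

#' Plant editing sites and SNP decoys on a synthetic reference
#'
#' Places `n_edit_sites` edits on sense-strand adenosines according to
#' the configured region mix; CDS sites draw their codon position from
#' `wobble_bias`. Each site gets a true efficiency from the configured
#' distribution and allelic depths `ad_alt ~ Binomial(read_depth,
#' efficiency)` (sites that draw `ad_alt = 0` are still emitted — the
#' caller must filter them). SNP decoys (`round(snp_rate *
#' n_edit_sites)`) are planted the same way, emitted in the variant set
#' and recorded in the blacklist. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param models,seqs output of [generate_reference()].
#' @return list with `variants` (data.frame as from [read_vcf()]),
#'   `truth` (planted ground truth incl. `is_snp_decoy`) and
#'   `blacklist` (decoy positions).
#' @export
plant_edits <- function(cfg, models, seqs) {
  set.seed(cfg$seed + 1L)
  n_decoys <- round(cfg$snp_rate * cfg$n_edit_sites)
  n_total <- cfg$n_edit_sites + n_decoys
  is_decoy <- c(rep(FALSE, cfg$n_edit_sites), rep(TRUE, n_decoys))
  used <- character(0)
  truth <- list()
  tx_ids <- names(models)
  n_eligible <- max(1L, round(cfg$fraction_transcripts_modified * length(tx_ids)))
  eligible <- sort(sample(tx_ids, n_eligible))
  regions <- names(cfg$region_mix)
  for (i in seq_len(n_total)) {
    placed <- FALSE
    for (attempt in 1:200) {
      pool <- if (is_decoy[i]) tx_ids else eligible
      t <- models[[sample(pool, 1L)]]
      region <- sample(regions, 1L, prob = cfg$region_mix)
      cand <- candidate_positions(t, seqs, region,
                                  wobble_bias = if (region == "cds") cfg$wobble_bias else NULL)
      if (!length(cand)) next
      cand <- cand[!paste(t$contig, cand) %in% used]
      if (!length(cand)) next
      gpos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      used <- c(used, paste(t$contig, gpos))
      eff <- draw_efficiency(cfg$efficiency, 1L)
      ad_alt <- stats::rbinom(1L, cfg$read_depth, eff)
      codon <- NA_character_
      cpos <- NA_integer_
      if (region == "cds") {
        ctx <- codon_context(t, gpos, seqs)
        codon <- ctx$codon_ref
        cpos <- ctx$codon_pos
      }
      truth[[i]] <- data.frame(
        contig = t$contig, gpos = gpos, transcript_id = t$transcript_id,
        strand = t$strand, region = region, codon = codon, codon_pos = cpos,
        true_efficiency = eff, ad_ref = cfg$read_depth - ad_alt,
        ad_alt = ad_alt, is_snp_decoy = is_decoy[i],
        stringsAsFactors = FALSE
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stopf("could not place edit %d: not enough adenosines for the configured region mix", i)
    }
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(contig = character(), gpos = integer(),
                        transcript_id = character(), strand = character(),
                        region = character(), codon = character(),
                        codon_pos = integer(), true_efficiency = numeric(),
                        ad_ref = integer(), ad_alt = integer(),
                        is_snp_decoy = logical(), stringsAsFactors = FALSE)
  }
  ref_allele <- ifelse(cfg$dialect == "genomic" & truth$strand == "-", "T", "A")
  alt_allele <- ifelse(cfg$dialect == "genomic" & truth$strand == "-", "C", "G")
  variants <- data.frame(
    contig = truth$contig, gpos = truth$gpos,
    ref = ref_allele, alt = alt_allele,
    ad_ref = truth$ad_ref, ad_alt = truth$ad_alt,
    sample_id = rep(cfg$sample_id, nrow(truth)), stringsAsFactors = FALSE
  )
  ord <- order(variants$contig, variants$gpos)
  blacklist <- truth[truth$is_snp_decoy, c("contig", "gpos"), drop = FALSE]
  rownames(blacklist) <- NULL
  list(variants = variants[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE],
       blacklist = blacklist[order(blacklist$contig, blacklist$gpos), , drop = FALSE])
}

#' Generate a synthetic abundance table
#'
#' Draws per-transcript TPMs spanning the TPM = 1 threshold: a
#' configured fraction falls uniformly below 1, the rest follow
#' 1 + LogNormal(meanlog, sdlog). A spike-in row is appended when
#' configured. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param models gene models from [generate_reference()].
#' @return an [abundance_table()].
#' @export
generate_abundance <- function(cfg, models) {
  set.seed(cfg$seed + 2L)
  ids <- names(models)
  n <- length(ids)
  n_below <- round(cfg$fraction_below_tpm1 * n)
  below <- sample(n, n_below)
  tpm <- numeric(n)
  tpm[below] <- stats::runif(n_below, 0.05, 0.95)
  tpm[-below] <- 1 + stats::rlnorm(n - n_below, cfg$tpm_meanlog, cfg$tpm_sdlog)
  df <- data.frame(transcript_id = ids, tpm = tpm, stringsAsFactors = FALSE)
  sid <- NULL; nominal <- NULL
  if (!is.null(cfg$spike_in)) {
    sid <- cfg$spike_in$id
    nominal <- cfg$spike_in$nominal_tpm
    df <- rbind(df, data.frame(transcript_id = sid,
                               tpm = nominal * (cfg$spike_in$observed_factor %||% 1),
                               stringsAsFactors = FALSE))
  }
  abundance_table(df, spike_in_id = sid, spike_in_nominal_tpm = nominal)
}

write_gff3_file <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (tid in names(models)) {
    t <- models[[tid]]
    gid <- t$gene_id
    lines <- c(
      sprintf("%s\tinoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              t$contig, t$span[1], t$span[2], t$strand, gid),
      sprintf("%s\tinoscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;biotype=%s",
              t$contig, t$span[1], t$span[2], t$strand, tid, gid, t$biotype)
    )
    for (k in seq_len(nrow(t$exons))) {
      lines <- c(lines, sprintf(
        "%s\tinoscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        t$contig, t$exons[k, 1], t$exons[k, 2], t$strand, tid, k, tid))
    }
    if (nrow(t$cds)) {
      # phase of each CDS piece in transcription order
      ord <- if (t$strand == "+") seq_len(nrow(t$cds)) else rev(seq_len(nrow(t$cds)))
      cum <- 0L
      phase <- integer(nrow(t$cds))
      for (k in ord) {
        phase[k] <- (3L - cum %% 3L) %% 3L
        cum <- cum + t$cds[k, 2] - t$cds[k, 1] + 1L
      }
      for (k in seq_len(nrow(t$cds))) {
        lines <- c(lines, sprintf(
          "%s\tinoscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
          t$contig, t$cds[k, 1], t$cds[k, 2], t$strand, phase[k], tid, tid))
      }
    }
    writeLines(lines, con)
  }
  invisible(path)
}

write_vcf_file <- function(variants, seqs, path, sample_id = "sample1") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=inoscan-simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(seqs), nchar(seqs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  writeLines(header, con)
  if (nrow(variants)) {
    v <- variants[order(variants$contig, variants$gpos), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                       v$contig, v$gpos, v$ref, v$alt,
                       v$ad_ref, v$ad_alt, v$ad_ref + v$ad_alt), con)
  }
  invisible(path)
}

write_tsv <- function(df, path, digits = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = digits %||% 10, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Emit a complete synthetic dataset to disk
#'
#' Generates a reference, gene models, planted edits and abundance
#' table under `cfg$seed` and writes `reference.fa`, `models.gff3`,
#' `variants.vcf`, `blacklist.tsv`, `abundance.tsv` and `truth.tsv`
#' into `outdir`. Two runs with identical configs produce byte-identical
#' files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with the file `paths` and the in-memory
#'   `seqs`, `models`, `variants`, `truth`, `blacklist`, `abundance`
#'   and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_reference(cfg)
  planted <- plant_edits(cfg, gen$models, gen$seqs)
  ab <- generate_abundance(cfg, gen$models)
  paths <- list(
    fasta = file.path(outdir, "reference.fa"),
    gff3 = file.path(outdir, "models.gff3"),
    vcf = file.path(outdir, "variants.vcf"),
    blacklist = file.path(outdir, "blacklist.tsv"),
    abundance = file.path(outdir, "abundance.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_fasta(gen$seqs, paths$fasta)
  write_gff3_file(gen$models, paths$gff3)
  write_vcf_file(planted$variants, gen$seqs, paths$vcf, cfg$sample_id)
  write_tsv(planted$blacklist, paths$blacklist)
  write_tsv(data.frame(transcript_id = ab$transcript_id, tpm = ab$tpm),
            paths$abundance)
  write_tsv(planted$truth, paths$truth)
  invisible(list(paths = paths, seqs = gen$seqs, models = gen$models,
                 variants = planted$variants, truth = planted$truth,
                 blacklist = planted$blacklist, abundance = ab,
                 config = cfg))
}
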