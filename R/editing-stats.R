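#' Number of unique modified transcripts
#'
#' A transcript is considered inosine-modified if it carries at least
#' one editing site; it is counted once regardless of how many sites it
#' carries.
#'
#' @param sites an `inosine_sites` data.frame.
#' @return integer count of distinct transcript ids.
#' @export
count_modified_transcripts <- function(sites) {
  length(unique(sites$transcript_id))
}

expressed_transcripts <- function(abundance, tpm_min = 1) {
  ab <- abundance
  if (inherits(ab, "abundance_table") && !is.null(attr(ab, "spike_in_id"))) {
    ab <- normalize_to_spike(ab)
  }
  ab$transcript_id[ab$tpm >= tpm_min]
}

#' Proportion of the expressed transcriptome that is modified
#'
#' @param sites an `inosine_sites` data.frame.
#' @param abundance an [abundance_table()].
#' @param tpm_min expression threshold defining the denominator
#'   (transcripts with TPM >= `tpm_min`).
#' @return list with `n_modified`, `n_expressed` and `proportion`.
#' @export
proportion_modified <- function(sites, abundance, tpm_min = 1) {
  expressed <- expressed_transcripts(abundance, tpm_min)
  n_mod <- length(intersect(unique(sites$transcript_id), expressed))
  list(n_modified = n_mod, n_expressed = length(expressed),
       proportion = if (length(expressed)) n_mod / length(expressed) else NA_real_)
}

#' Restrict samples to commonly expressed transcripts
#'
#' Keeps only sites on transcripts expressed (TPM >= `tpm_min`) in
#' every sample, so between-group comparisons are not confounded by
#' differential expression.
#'
#' @param site_list named list of `inosine_sites` data.frames, one per
#'   sample.
#' @param abundance_list named list of [abundance_table()]s, parallel
#'   to `site_list`.
#' @param tpm_min expression threshold.
#' @return list with `sites` (the restricted site list) and
#'   `common_transcripts` (ids expressed in every sample).
#' @export
restrict_to_common <- function(site_list, abundance_list, tpm_min = 1) {
  stopifnot(length(site_list) >= 2, length(site_list) == length(abundance_list))
  sets <- lapply(abundance_list, expressed_transcripts, tpm_min = tpm_min)
  common <- Reduce(intersect, sets)
  out <- lapply(site_list, function(s) {
    s[s$transcript_id %in% common, , drop = FALSE]
  })
  list(sites = out, common_transcripts = common)
}

#' Histogram of editing sites per transcript
#'
#' @param sites an `inosine_sites` data.frame.
#' @return named integer vector: names are site counts k, values the
#'   number of transcripts carrying exactly k sites.
#' @export
modifications_per_transcript <- function(sites) {
  if (!nrow(sites)) return(stats::setNames(integer(0), character(0)))
  per_tx <- table(sites$transcript_id)
  tab <- table(factor(as.integer(per_tx)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Distribution of sites over transcript regions
#'
#' @param sites an `inosine_sites` data.frame.
#' @return named integer vector over the region labels (5' UTR, CDS,
#'   intron, 3' UTR, noncoding exon); counts sum to `nrow(sites)`.
#' @export
region_distribution <- function(sites) {
  tab <- table(factor(sites$region, levels = region_levels()))
  stats::setNames(as.integer(tab), names(tab))
}

drop_stop_events <- function(contexts) {
  contexts[!contexts$consequence %in%
             c("stop_lost", "stop_gained", "stop_retained"), , drop = FALSE]
}

#' Editing-site counts per adenosine-containing codon
#'
#' Counts sites per reference codon over the 34 adenosine-containing
#' non-stop codons (absent codons are reported as 0), and per
#' (codon, position) class. Stop-altering events are excluded, as they
#' are from all downstream codon statistics.
#'
#' @param contexts codon contexts from [annotate_codons()].
#' @return list with `by_codon` (named integer vector, 34 entries) and
#'   `by_codon_pos` (data.frame `codon`, `codon_pos`, `count`).
#' @export
per_codon_counts <- function(contexts) {
  contexts <- drop_stop_events(contexts)
  codons <- adenosine_codons()
  if (nrow(contexts) && !all(grepl("A", contexts$codon_ref))) {
    stopf("internal error: context codon without adenosine")
  }
  by_codon <- table(factor(contexts$codon_ref, levels = codons))
  bp <- as.data.frame(table(
    codon = factor(contexts$codon_ref, levels = codons),
    codon_pos = factor(contexts$codon_pos, levels = 1:3)
  ), stringsAsFactors = FALSE)
  names(bp)[3] <- "count"
  bp$codon_pos <- as.integer(bp$codon_pos)
  bp <- bp[bp$count > 0 |
             mapply(function(c, p) substring(c, p, p) == "A", bp$codon, bp$codon_pos),
           , drop = FALSE]
  rownames(bp) <- NULL
  list(by_codon = stats::setNames(as.integer(by_codon), codons),
       by_codon_pos = bp)
}

#' Frequencies of editing at the three codon positions
#'
#' @param contexts codon contexts from [annotate_codons()].
#' @return numeric triple `(f1, f2, f3)` summing to 1; `f3` is the
#'   wobble-position frequency. All-NA triple when no CDS context
#'   exists (with a warning). Stop-altering events are excluded.
#' @export
codon_position_frequencies <- function(contexts) {
  contexts <- drop_stop_events(contexts)
  if (!nrow(contexts)) {
    warnf("no CDS contexts; position frequencies undefined")
    return(stats::setNames(rep(NA_real_, 3), paste0("f", 1:3)))
  }
  counts <- table(factor(contexts$codon_pos, levels = 1:3))
  stats::setNames(as.numeric(counts) / sum(counts), paste0("f", 1:3))
}

#' Adenosine availability at the three codon positions
#'
#' The fraction of adenosines found at codon positions 1, 2 and 3
#' across the CDSs of the given transcripts — the null expectation for
#' the wobble enrichment test when editing is proportional to available
#' adenosines.
#'
#' @param models list of [transcript_model()] objects.
#' @param ref reference sequences from [read_fasta()].
#' @param transcript_ids transcripts to include (default: all complete
#'   CDS transcripts in `models`).
#' @return numeric triple summing to 1.
#' @export
codon_position_availability <- function(models, ref, transcript_ids = NULL) {
  if (is.null(transcript_ids)) {
    transcript_ids <- names(Filter(function(t) t$cds_complete, models))
  }
  counts <- c(0L, 0L, 0L)
  for (tid in transcript_ids) {
    t <- models[[tid]]
    if (is.null(t) || !t$cds_complete) next
    s <- cds_sequence(t, ref)
    bases <- strsplit(s, "")[[1]]
    pos <- rep_len(1:3, length(bases))
    a <- bases == "A"
    counts <- counts + vapply(1:3, function(p) sum(a & pos == p), integer(1))
  }
  if (sum(counts) == 0) stopf("no adenosines found in the given CDSs")
  stats::setNames(counts / sum(counts), paste0("p", 1:3))
}

#' Chi-square test for codon-position (wobble) enrichment
#'
#' Pearson chi-square test of the observed editing-site counts at codon
#' positions 1-3 against expected proportions. The natural null is
#' proportionality to the available adenosines at each position
#' (supply `availability` from [codon_position_availability()]); when
#' `availability` is omitted, a uniform 1/3 null is used. No continuity
#' correction is applied.
#'
#' @param contexts codon contexts from [annotate_codons()], or a
#'   length-3 vector of observed counts.
#' @param availability expected proportions at positions 1-3 (need not
#'   be normalized); `NULL` for the uniform null.
#' @return object of class `group_comparison` with the chi-square
#'   statistic, degrees of freedom and p-value.
#' @export
wobble_enrichment_test <- function(contexts, availability = NULL) {
  obs <- if (is.numeric(contexts) && length(contexts) == 3) {
    as.numeric(contexts)
  } else {
    contexts <- drop_stop_events(contexts)
    if (!nrow(contexts)) stopf("no CDS contexts to test")
    as.numeric(table(factor(contexts$codon_pos, levels = 1:3)))
  }
  p <- if (is.null(availability)) rep(1 / 3, 3) else availability / sum(availability)
  if (any(p * sum(obs) == 0)) {
    stopf("zero expected count in a codon-position cell; pool positions before testing")
  }
  ht <- suppressWarnings(stats::chisq.test(obs, p = p, correct = FALSE))
  group_comparison(
    statistic_name = "chi_square",
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    df = unname(ht$parameter),
    groups = data.frame(position = 1:3, observed = obs,
                        expected = unname(ht$expected))
  )
}

#' Mean editing efficiency per (codon, position) class
#'
#' @param contexts codon contexts from [annotate_codons()] (they carry
#'   per-site `efficiency` and allelic depths).
#' @param method `"mean"` (default): unweighted mean of per-site
#'   efficiencies; `"pooled"`: read-pooled ratio
#'   `sum(ad_alt) / sum(ad_ref + ad_alt)`.
#' @return data.frame `codon`, `codon_pos`, `codon_class` (codon
#'   written with the edited position capitalised, e.g. `"aAa"`),
#'   `n_sites`, `efficiency`; classes with no sites are omitted.
#'   Stop-altering events are excluded.
#' @export
per_codon_efficiency <- function(contexts, method = c("mean", "pooled")) {
  method <- match.arg(method)
  contexts <- drop_stop_events(contexts)
  if (!nrow(contexts)) {
    return(data.frame(codon = character(), codon_pos = integer(),
                      codon_class = character(), n_sites = integer(),
                      efficiency = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(contexts$codon_ref, contexts$codon_pos)
  groups <- split(contexts, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    eff <- if (method == "mean") mean(g$efficiency)
           else sum(g$ad_alt) / sum(g$ad_ref + g$ad_alt)
    data.frame(codon = g$codon_ref[1], codon_pos = g$codon_pos[1],
               n_sites = nrow(g), efficiency = eff, stringsAsFactors = FALSE)
  }))
  cls <- tolower(out$codon)
  substring(cls, out$codon_pos, out$codon_pos) <-
    toupper(substring(cls, out$codon_pos, out$codon_pos))
  out$codon_class <- cls
  out <- out[order(out$codon, out$codon_pos),
             c("codon", "codon_pos", "codon_class", "n_sites", "efficiency")]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between editing efficiency and abundance
#'
#' Correlates per-transcript mean editing efficiency with transcript
#' TPM across modified transcripts.
#'
#' @param sites an `inosine_sites` data.frame.
#' @param abundance an [abundance_table()].
#' @return object of class `group_comparison` with `statistic_name =
#'   "pearson"`, the correlation as statistic, and a two-sided p-value;
#'   statistic is `NA` (with a note) when either variable has zero
#'   variance.
#' @export
efficiency_abundance_correlation <- function(sites, abundance) {
  ab <- abundance
  if (inherits(ab, "abundance_table") && !is.null(attr(ab, "spike_in_id"))) {
    ab <- normalize_to_spike(ab)
  }
  eff <- tapply(sites$efficiency, sites$transcript_id, mean)
  tpm <- stats::setNames(ab$tpm, ab$transcript_id)[names(eff)]
  keep <- !is.na(tpm)
  eff <- as.numeric(eff[keep]); tpm <- as.numeric(tpm[keep])
  if (length(eff) < 3) stopf("need >= 3 transcripts with both efficiency and TPM")
  if (stats::sd(eff) == 0 || stats::sd(tpm) == 0) {
    return(group_comparison("pearson", NA_real_, NA_real_,
                            note = "zero variance; correlation undefined",
                            n = length(eff)))
  }
  ht <- stats::cor.test(eff, tpm, method = "pearson")
  group_comparison("pearson", unname(ht$estimate), unname(ht$p.value),
                   df = unname(ht$parameter), n = length(eff))
}

group_comparison <- function(statistic_name, statistic, p_value,
                             df = NULL, groups = NULL, table = NULL,
                             note = NULL, n = NULL) {
  structure(
    list(statistic_name = statistic_name, statistic = statistic,
         p_value = p_value, df = df, groups = groups, table = table,
         note = note, n = n),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- switch(x$statistic_name,
                chi_square = "Chi-square", one_way_anova = "One-way ANOVA F",
                two_way_anova = "Two-way ANOVA F (first factor)",
                pearson = "Pearson r", x$statistic_name)
  cat(sprintf("%s = %.4g%s, p = %.4g\n", lab, x$statistic,
              if (!is.null(x$df)) sprintf(" (df %s)", paste(x$df, collapse = ", ")) else "",
              x$p_value))
  if (!is.null(x$groups)) print(x$groups)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

sem <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Compare editing summaries across groups
#'
#' Group-comparison tests used throughout the analysis: one-way ANOVA
#' across genotype groups, two-way ANOVA across genotype x category
#' cells, and Pearson chi-square for proportion (contingency-table)
#' designs. Group means are reported with SEM; note that SEM over n = 2
#' replicates (a common replicate count in these designs) is unstable.
#'
#' @param x for `"one_way"`: a named list of numeric vectors (one per
#'   group); for `"two_way"`: a data.frame with columns `value`,
#'   `genotype`, `category`; for `"proportions"`: a contingency matrix
#'   of counts.
#' @param design `"one_way"`, `"two_way"` or `"proportions"`.
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(x, design = c("one_way", "two_way", "proportions")) {
  design <- match.arg(design)
  if (design == "one_way") {
    stopifnot(is.list(x), length(x) >= 2)
    df <- data.frame(
      value = unlist(x, use.names = FALSE),
      group = rep(names(x) %||% paste0("g", seq_along(x)),
                  lengths(x))
    )
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    gm <- do.call(rbind, lapply(split(df$value, df$group), function(v) {
      data.frame(mean = mean(v), sem = sem(v), n = length(v))
    }))
    gm$group <- rownames(gm); rownames(gm) <- NULL
    if (any(gm$n == 2)) {
      warnf("SEM computed over n = 2 replicates is unstable")
    }
    return(group_comparison("one_way_anova",
                            statistic = an[["F value"]][1],
                            p_value = an[["Pr(>F)"]][1],
                            df = an[["Df"]],
                            groups = gm[, c("group", "mean", "sem", "n")],
                            table = an))
  }
  if (design == "two_way") {
    stopifnot(all(c("value", "genotype", "category") %in% names(x)))
    x$genotype <- factor(x$genotype)
    x$category <- factor(x$category)
    reps <- max(table(x$genotype, x$category))
    form <- if (reps >= 2) value ~ genotype * category else value ~ genotype + category
    fit <- stats::aov(form, data = x)
    an <- summary(fit)[[1]]
    gm <- do.call(rbind, lapply(split(x$value, list(x$genotype, x$category)),
                                function(v) data.frame(mean = mean(v),
                                                       sem = sem(v), n = length(v))))
    gm$cell <- rownames(gm); rownames(gm) <- NULL
    return(group_comparison("two_way_anova",
                            statistic = an[["F value"]][1],
                            p_value = an[["Pr(>F)"]][1],
                            df = an[["Df"]],
                            groups = gm[, c("cell", "mean", "sem", "n")],
                            table = an))
  }
  # proportions: Pearson chi-square without continuity correction
  stopifnot(is.matrix(x))
  ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  group_comparison("chi_square", unname(ht$statistic), unname(ht$p.value),
                   df = unname(ht$parameter), table = ht$observed)
}

#' Per-sample editing summary
#'
#' Bundles the per-sample statistics: unique modified-transcript count,
#' proportion of the expressed transcriptome modified, sites-per-
#' transcript histogram, region distribution, per-codon counts,
#' codon-position frequencies and per-codon efficiency.
#'
#' @param sites an `inosine_sites` data.frame.
#' @param abundance an [abundance_table()].
#' @param contexts optional codon contexts from [annotate_codons()];
#'   codon-level components are NULL when omitted.
#' @param sample_id sample label.
#' @param tpm_min expression threshold for the denominator.
#' @return object of class `editing_summary`.
#' @export
summarize_editing <- function(sites, abundance, contexts = NULL,
                              sample_id = NULL, tpm_min = 1) {
  pm <- proportion_modified(sites, abundance, tpm_min)
  out <- list(
    sample_id = sample_id %||% (if (nrow(sites)) sites$sample_id[1] else NA_character_),
    n_sites = nrow(sites),
    n_modified_transcripts = count_modified_transcripts(sites),
    n_expressed_transcripts = pm$n_expressed,
    proportion_modified = pm$proportion,
    per_transcript_histogram = modifications_per_transcript(sites),
    region_counts = region_distribution(sites),
    mean_efficiency = if (nrow(sites)) mean(sites$efficiency) else NA_real_
  )
  if (!is.null(contexts)) {
    out$codon_counts <- per_codon_counts(contexts)
    out$position_frequencies <- if (nrow(drop_stop_events(contexts))) {
      codon_position_frequencies(contexts)
    } else NULL
    out$per_codon_efficiency <- per_codon_efficiency(contexts)
    out$consequence_counts <- table(contexts$consequence)
  }
  structure(out, class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("<editing_summary> sample %s\n", x$sample_id))
  cat(sprintf("  %d sites on %d modified transcripts / %d expressed (%.1f%%)\n",
              x$n_sites, x$n_modified_transcripts, x$n_expressed_transcripts,
              100 * x$proportion_modified))
  cat("  region counts: ",
      paste(sprintf("%s=%d", names(x$region_counts), x$region_counts),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$position_frequencies)) {
    cat(sprintf("  codon position frequencies: %.3f / %.3f / %.3f (wobble)\n",
                x$position_frequencies[1], x$position_frequencies[2],
                x$position_frequencies[3]))
  }
  if (!is.na(x$mean_efficiency)) {
    cat(sprintf("  mean editing efficiency: %.3f\n", x$mean_efficiency))
  }
  invisible(x)
}
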