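#' Pipeline configuration
#'
#' Assembles a run configuration for [run_all()]: either a `simulate`
#' block (a [sim_config()]) or an `inputs` block pointing at existing
#' files.
#'
#' @param inputs named list of paths: `fasta`, `gff3`, `vcf`,
#'   `abundance`, and optionally `blacklist`; plus optional `sample`
#'   (VCF sample name) and spike-in settings `spike_in_id`,
#'   `spike_in_nominal_tpm`.
#' @param simulate a [sim_config()]; when given, inputs are generated
#'   into `<outdir>/simulated` first.
#' @param dialect allele orientation of the VCF (`"sense"` or
#'   `"genomic"`).
#' @param tpm_min minimum host-transcript TPM (default 1).
#' @param min_ad_alt minimum alternate-allele depth (default 1).
#' @param isoform isoform handling for codon analyses (`"canonical"`
#'   or `"all"`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            dialect = c("sense", "genomic"),
                            tpm_min = 1, min_ad_alt = 1,
                            isoform = c("canonical", "all")) {
  dialect <- match.arg(dialect)
  isoform <- match.arg(isoform)
  if (is.null(inputs) && is.null(simulate)) {
    stopf("pipeline_config needs either `inputs` or `simulate`")
  }
  structure(list(inputs = inputs, simulate = simulate, dialect = dialect,
                 tpm_min = tpm_min, min_ad_alt = min_ad_alt,
                 isoform = isoform),
            class = "pipeline_config")
}

#' Run the full editing analysis pipeline
#'
#' Orchestrates the stages: (optional) simulation, input loading, site
#' calling, codon annotation, and statistics. Writes one TSV per
#' figure-style analysis (`sites.tsv`, `fig1_counts.tsv`,
#' `fig2_proportions.tsv`, `fig2c_histogram.tsv`, `fig2d_regions.tsv`,
#' `fig4_codon_counts.tsv`, `fig5_positions.tsv`,
#' `fig6_efficiency.tsv`, `stats_tests.tsv`), a run-level
#' `summary.json` (filter tallies and headline numbers) and a
#' `run_manifest.json` recording the config digest, input/output file
#' digests, seed and stage timings. Reruns with the same config and
#' seed produce byte-identical analysis outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return (invisibly) an object of class `inosine_run`: the manifest
#'   plus the in-memory `sites`, `contexts` and `summary`.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate, file.path(outdir, "simulated"))
    inputs <- sim$paths
    sample <- config$simulate$sample_id
    spike_id <- config$simulate$spike_in$id
    spike_nominal <- config$simulate$spike_in$nominal_tpm
    if (is.null(config$inputs) && config$simulate$dialect != config$dialect) {
      config$dialect <- config$simulate$dialect
    }
    timings["simulate"] <- tic() - t0
  } else {
    inputs <- config$inputs
    sample <- config$inputs$sample %||% NULL
    spike_id <- config$inputs$spike_in_id %||% NULL
    spike_nominal <- config$inputs$spike_in_nominal_tpm %||% NULL
  }

  required <- c("fasta", "gff3", "vcf", "abundance")
  for (f in required) {
    if (is.null(inputs[[f]]) || !file.exists(inputs[[f]])) {
      stopf("input file not found: %s (%s)", inputs[[f]] %||% "<missing>", f)
    }
  }
  input_paths <- unlist(inputs[names(inputs) %in%
                                 c(required, "blacklist", "truth")])
  input_digests <- tools::md5sum(input_paths)

  t1 <- tic()
  ref <- read_fasta(inputs$fasta)
  models <- read_gene_models(inputs$gff3)
  variants <- read_vcf(inputs$vcf, sample = sample)
  abundance <- read_abundance(inputs$abundance,
                              spike_in_id = spike_id,
                              spike_in_nominal_tpm = spike_nominal)
  blacklist <- if (!is.null(inputs$blacklist) && file.exists(inputs$blacklist)) {
    read_blacklist(inputs$blacklist)
  } else NULL
  timings["load"] <- tic() - t1

  t2 <- tic()
  sites <- call_inosine_sites(variants, models, abundance,
                              blacklist = blacklist,
                              dialect = config$dialect,
                              tpm_min = config$tpm_min,
                              min_ad_alt = config$min_ad_alt)
  timings["call"] <- tic() - t2

  t3 <- tic()
  contexts <- annotate_codons(sites, models, ref, isoform = config$isoform)
  timings["annotate"] <- tic() - t3

  t4 <- tic()
  summ <- summarize_editing(sites, abundance, contexts,
                            sample_id = sample %||% "sample1",
                            tpm_min = config$tpm_min)
  expressed <- expressed_transcripts(abundance, config$tpm_min)
  avail <- codon_position_availability(
    models, ref, intersect(expressed, names(Filter(function(t) t$cds_complete, models))))
  tests <- list()
  ctx_ns <- drop_stop_events(contexts)
  if (nrow(ctx_ns) > 0) {
    tests$wobble_vs_availability <- tryCatch(
      wobble_enrichment_test(contexts, availability = avail),
      error = function(e) NULL)
    tests$wobble_vs_uniform <- tryCatch(
      wobble_enrichment_test(contexts), error = function(e) NULL)
    tests <- Filter(Negate(is.null), tests)
  }
  n_eff_tx <- length(unique(sites$transcript_id))
  if (n_eff_tx >= 3) {
    corr <- tryCatch(efficiency_abundance_correlation(sites, abundance),
                     error = function(e) NULL)
    if (!is.null(corr)) tests$efficiency_abundance <- corr
  }
  timings["stats"] <- tic() - t4

  # ---- outputs -------------------------------------------------------
  outputs <- c(
    sites = "sites.tsv", fig1 = "fig1_counts.tsv",
    fig2 = "fig2_proportions.tsv", fig2c = "fig2c_histogram.tsv",
    fig2d = "fig2d_regions.tsv", fig4 = "fig4_codon_counts.tsv",
    fig5 = "fig5_positions.tsv", fig6 = "fig6_efficiency.tsv",
    tests = "stats_tests.tsv", summary = "summary.json"
  )
  outputs <- stats::setNames(file.path(outdir, outputs), names(outputs))

  write_tsv(as.data.frame(sites), outputs["sites"])
  write_tsv(data.frame(sample_id = summ$sample_id,
                       n_modified_transcripts = summ$n_modified_transcripts),
            outputs["fig1"])
  write_tsv(data.frame(sample_id = summ$sample_id,
                       n_modified = summ$n_modified_transcripts,
                       n_expressed = summ$n_expressed_transcripts,
                       proportion = summ$proportion_modified),
            outputs["fig2"])
  hist <- summ$per_transcript_histogram
  write_tsv(data.frame(sites_per_transcript = as.integer(names(hist)),
                       n_transcripts = as.integer(hist)),
            outputs["fig2c"])
  write_tsv(data.frame(region = names(summ$region_counts),
                       count = as.integer(summ$region_counts)),
            outputs["fig2d"])
  cc <- summ$codon_counts
  write_tsv(data.frame(codon = names(cc$by_codon),
                       count = as.integer(cc$by_codon)),
            outputs["fig4"])
  pf <- summ$position_frequencies
  write_tsv(data.frame(codon_pos = 1:3,
                       frequency = if (is.null(pf)) rep(NA_real_, 3) else as.numeric(pf)),
            outputs["fig5"])
  write_tsv(summ$per_codon_efficiency, outputs["fig6"])
  test_rows <- do.call(rbind, lapply(names(tests), function(nm) {
    tt <- tests[[nm]]
    data.frame(test = nm, statistic_name = tt$statistic_name,
               statistic = tt$statistic, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  }))
  write_tsv(test_rows %||% data.frame(test = character(),
                                      statistic_name = character(),
                                      statistic = numeric(),
                                      p_value = numeric()),
            outputs["tests"])
  summary_json <- list(
    sample_id = summ$sample_id,
    filter_tally = as.list(attr(sites, "filter_tally")),
    n_sites = summ$n_sites,
    n_modified_transcripts = summ$n_modified_transcripts,
    n_expressed_transcripts = summ$n_expressed_transcripts,
    proportion_modified = summ$proportion_modified,
    mean_efficiency = summ$mean_efficiency,
    position_frequencies = if (is.null(pf)) NULL else as.list(pf),
    consequence_counts = if (!is.null(summ$consequence_counts)) {
      as.list(stats::setNames(as.integer(summ$consequence_counts),
                              names(summ$consequence_counts)))
    } else NULL,
    tests = lapply(tests, function(tt) list(statistic_name = tt$statistic_name,
                                            statistic = tt$statistic,
                                            p_value = tt$p_value))
  )
  jsonlite::write_json(summary_json, outputs["summary"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  manifest <- list(
    config_digest = unname(tools::md5sum(cfg_path)),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NULL,
    input_digests = as.list(input_digests),
    output_digests = as.list(tools::md5sum(unname(outputs))),
    filter_tally = as.list(attr(sites, "filter_tally")),
    timings_sec = as.list(round(timings, 3)),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(structure(
    list(manifest = manifest, sites = sites, contexts = contexts,
         summary = summ, tests = tests, outdir = outdir),
    class = "inosine_run"
  ))
}

config_to_list <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

#' @export
print.inosine_run <- function(x, ...) {
  cat(sprintf("<inosine_run> %s\n", x$outdir))
  print(x$summary)
  invisible(x)
}
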