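toy_vcf <- function(records) {
  write_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    records
  ), ".vcf")
}

test_that("read_vcf extracts AD, splits multiallelics and skips indels", {
  p <- toy_vcf(c(
    "c1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:5,7",
    "c1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT:AD\t0/1:10,3,2",
    "c1\t300\t.\tA\tAG\t.\tPASS\t.\tGT:AD\t0/1:4,4"
  ))
  v <- suppressWarnings(read_vcf(p))
  expect_identical(nrow(v), 3L)  # 1 + 2 split alleles; insertion skipped
  expect_identical(v$ad_ref[1], 5L)
  expect_identical(v$ad_alt[1], 7L)
  split <- v[v$gpos == 200, ]
  expect_setequal(split$alt, c("G", "T"))
  expect_identical(split$ad_alt[split$alt == "G"], 3L)
  expect_identical(split$ad_alt[split$alt == "T"], 2L)
  expect_warning(read_vcf(p), "skipped")
  expect_error(read_vcf(p, sample = "nope"), "not in the VCF|sample")
})

test_that("filter_known_snps is a pure positional set difference", {
  v <- data.frame(contig = "c1", gpos = c(10L, 20L, 30L), ref = "A",
                  alt = "G", ad_ref = 1L, ad_alt = 1L, sample_id = "s")
  bl <- data.frame(contig = "c1", gpos = 20L)
  expect_identical(filter_known_snps(v, bl)$gpos, c(10L, 30L))
  expect_identical(filter_known_snps(v, NULL), v)
  expect_identical(filter_known_snps(v, bl[0, ]), v)
  all_bl <- data.frame(contig = "c1", gpos = c(10L, 20L, 30L))
  expect_identical(nrow(filter_known_snps(v, all_bl)), 0L)
})

test_that("read_blacklist accepts TSV (with/without header) and VCF", {
  tsv <- write_tmp(c("contig\tpos", "c1\t20", "c2\t30"), ".tsv")
  bl <- read_blacklist(tsv)
  expect_identical(bl$gpos, c(20L, 30L))
  tsv2 <- write_tmp(c("c1\t20"), ".tsv")
  expect_identical(read_blacklist(tsv2)$gpos, 20L)
  vcf <- toy_vcf("c1\t55\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:5,5")
  expect_identical(read_blacklist(vcf)$gpos, 55L)
})

test_that("orient_to_sense complements only under the genomic dialect on minus strand", {
  expect_identical(orient_to_sense("T", "C", "-", "genomic"),
                   list(ref = "A", alt = "G"))
  expect_identical(orient_to_sense("A", "G", "+", "genomic"),
                   list(ref = "A", alt = "G"))
  # genomic A>G on a minus-strand transcript is sense T>C: not an edit
  expect_identical(orient_to_sense("A", "G", "-", "genomic"),
                   list(ref = "T", alt = "C"))
  expect_identical(orient_to_sense("T", "C", "-", "sense"),
                   list(ref = "T", alt = "C"))
})

test_that("spike-in normalization rescales and drops the spike row", {
  ab <- abundance_table(c(t1 = 4, t2 = 8, spike = 200),
                        spike_in_id = "spike", spike_in_nominal_tpm = 100)
  out <- normalize_to_spike(ab)
  expect_false("spike" %in% out$transcript_id)
  expect_equal(out$tpm, c(2, 4))  # observed 2x nominal -> halved
  # observed == nominal -> identity
  ab2 <- abundance_table(c(t1 = 4, spike = 100),
                         spike_in_id = "spike", spike_in_nominal_tpm = 100)
  expect_equal(normalize_to_spike(ab2)$tpm, 4)
  ab3 <- abundance_table(c(t1 = 4, spike = 0),
                         spike_in_id = "spike", spike_in_nominal_tpm = 100)
  expect_error(normalize_to_spike(ab3), "zero")
  expect_error(abundance_table(c(t1 = 1), spike_in_id = "spike"),
               "not present")
})

caller_fixture <- function() {
  # two genes; tx_plus on c1 (+), tx_minus on c2 (-)
  list(
    models = list(
      tx_plus = transcript_model("tx_plus", "g1", "c1", "+",
                                 exons = cbind(1L, 30L), cds = cbind(7L, 24L)),
      tx_minus = transcript_model("tx_minus", "g2", "c2", "-",
                                  exons = cbind(1L, 30L), cds = cbind(7L, 24L))
    ),
    abundance = abundance_table(c(tx_plus = 2.0, tx_minus = 0.5))
  )
}

test_that("call_inosine_sites applies every filter and annotates", {
  f <- caller_fixture()
  v <- data.frame(
    contig = c("c1", "c1", "c1", "c2", "c1"),
    gpos   = c(10L,  12L,  14L,  10L,  16L),
    ref    = c("A",  "A",  "A",  "A",  "C"),
    alt    = c("G",  "G",  "G",  "G",  "T"),
    ad_ref = c(6L,   5L,   9L,   5L,   5L),
    ad_alt = c(4L,   0L,   1L,   5L,   5L),
    sample_id = "s1", stringsAsFactors = FALSE
  )
  bl <- data.frame(contig = "c1", gpos = 14L)
  out <- call_inosine_sites(v, f$models, f$abundance, blacklist = bl,
                            dialect = "sense")
  # passes: only the first record (AD>0, tpm 2.0, not blacklisted, A>G)
  expect_identical(nrow(out), 1L)
  expect_identical(out$transcript_id, "tx_plus")
  expect_identical(out$region, "cds")
  expect_equal(out$efficiency, 0.4)
  expect_identical(out$transcript_pos, 10L)
  tally <- attr(out, "filter_tally")
  expect_identical(unname(tally["known_snp"]), 1L)
  expect_identical(unname(tally["low_ad"]), 1L)
  expect_identical(unname(tally["low_tpm"]), 1L)  # tx_minus tpm 0.5
  expect_identical(unname(tally["not_a_to_g"]), 1L)
})

test_that("dialects treat minus-strand variants oppositely", {
  f <- caller_fixture()
  ab <- abundance_table(c(tx_plus = 2, tx_minus = 2))
  v <- data.frame(contig = "c2", gpos = 10L, ref = "T", alt = "C",
                  ad_ref = 3L, ad_alt = 7L, sample_id = "s1")
  # genomic dialect: T>C on minus strand is sense A>G
  out_g <- call_inosine_sites(v, f$models, ab, dialect = "genomic")
  expect_identical(nrow(out_g), 1L)
  expect_identical(out_g$ref, "A")
  # sense dialect: T>C stays T>C, rejected
  out_s <- call_inosine_sites(v, f$models, ab, dialect = "sense")
  expect_identical(nrow(out_s), 0L)
})

test_that("every returned site satisfies the filter invariants", {
  sim <- default_sim()
  out <- call_inosine_sites(sim$variants, sim$models, sim$abundance,
                            blacklist = sim$blacklist,
                            dialect = sim$config$dialect)
  expect_true(all(out$ref == "A" & out$alt == "G"))
  expect_true(all(out$ad_alt >= 1))
  expect_true(all(out$efficiency > 0 & out$efficiency <= 1))
  abn <- normalize_to_spike(sim$abundance)
  tpm <- setNames(abn$tpm, abn$transcript_id)
  expect_true(all(tpm[out$transcript_id] >= 1))
  expect_false(any(paste(out$contig, out$gpos) %in%
                     paste(sim$blacklist$contig, sim$blacklist$gpos)))
  # deterministic ordering
  expect_identical(order(out$contig, out$gpos, out$transcript_id),
                   seq_len(nrow(out)))
})

test_that("the final site set is independent of filter order", {
  sim <- default_sim()
  abn <- normalize_to_spike(sim$abundance)
  tpm <- setNames(abn$tpm, abn$transcript_id)
  # build the raw (variant x transcript) candidate table, then apply the
  # predicates in random orders
  v <- sim$variants
  by_contig <- split(sim$models,
                     vapply(sim$models, `[[`, character(1), "contig"))
  pairs <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    tx <- by_contig[[v$contig[i]]]
    hits <- Filter(function(t) v$gpos[i] >= t$span[1] && v$gpos[i] <= t$span[2], tx)
    if (!length(hits)) return(NULL)
    do.call(rbind, lapply(hits, function(t) {
      o <- orient_to_sense(v$ref[i], v$alt[i], t$strand, sim$config$dialect)
      cbind(v[i, ], transcript_id = t$transcript_id,
            sense_ref = o$ref, sense_alt = o$alt)
    }))
  }))
  preds <- list(
    snp = function(d) d[!paste(d$contig, d$gpos) %in%
                          paste(sim$blacklist$contig, sim$blacklist$gpos), ],
    ag  = function(d) d[d$sense_ref == "A" & d$sense_alt == "G", ],
    ad  = function(d) d[d$ad_alt >= 1, ],
    tpm = function(d) d[!is.na(tpm[d$transcript_id]) & tpm[d$transcript_id] >= 1, ]
  )
  reference <- call_inosine_sites(sim$variants, sim$models, sim$abundance,
                                  blacklist = sim$blacklist,
                                  dialect = sim$config$dialect)
  ref_key <- sort(paste(reference$contig, reference$gpos, reference$transcript_id))
  set.seed(3)
  for (rep in 1:8) {
    d <- pairs
    for (f in sample(preds)) d <- f(d)
    expect_identical(sort(paste(d$contig, d$gpos, d$transcript_id)), ref_key)
  }
})

test_that("no planted edits means no called sites", {
  cfg <- sim_config(seed = 9, n_genes = 8L, n_edit_sites = 0L, snp_rate = 0)
  gen <- generate_reference(cfg)
  planted <- plant_edits(cfg, gen$models, gen$seqs)
  ab <- generate_abundance(cfg, gen$models)
  out <- call_inosine_sites(planted$variants, gen$models, ab,
                            blacklist = planted$blacklist)
  expect_identical(nrow(out), 0L)
})
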