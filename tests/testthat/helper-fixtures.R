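# Shared fixtures: tiny hand-built references/models and a cached
# default simulation (generated once per test run).

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 42) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .sim_cache)) {
    dir <- file.path(tempdir(), paste0("inoscan-sim-", seed))
    assign(key, simulate_dataset(sim_config(seed = seed), dir),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# single-exon transcript: exon 1-30, CDS 7-24 (18 nt, 6 codons)
toy_single <- function(strand = "+") {
  transcript_model("tx1", "g1", "chr1", strand,
                   exons = cbind(1L, 30L), cds = cbind(7L, 24L))
}

# two-exon transcript with a junction inside the CDS
toy_two_exon <- function(strand = "+") {
  transcript_model("tx2", "g2", "chr1", strand,
                   exons = rbind(c(1L, 10L), c(21L, 30L)),
                   cds = rbind(c(5L, 10L), c(21L, 26L)))
}

# random two-exon toy with CDS spanning the junction; returns the model
# and its contig sequence
random_junction_toy <- function() {
  e1 <- sample(6:12, 1)   # exon1: 1..e1
  gap <- sample(3:8, 1)
  e2_start <- e1 + gap + 1L
  e2_len <- sample(6:12, 1)
  e2_end <- e2_start + e2_len - 1L
  total_exonic <- e1 + e2_len
  cds_len <- 3L * sample(2:(total_exonic %/% 3), 1)
  cds_start_t <- sample(seq_len(total_exonic - cds_len + 1L), 1)  # transcript coord, plus layout
  seq <- paste(sample(c("A", "C", "G", "T"), e2_end, replace = TRUE),
               collapse = "")
  strand <- sample(c("+", "-"), 1)
  # transcript-coordinate CDS (in plus layout) -> genomic intervals
  t2g_plus <- c(seq_len(e1), seq(e2_start, e2_end))
  cds_t <- seq(cds_start_t, cds_start_t + cds_len - 1L)
  gpos <- t2g_plus[cds_t]
  brk <- which(diff(gpos) > 1)
  cds_iv <- if (length(brk)) {
    cbind(c(gpos[1], gpos[brk + 1]), c(gpos[brk], gpos[length(gpos)]))
  } else {
    matrix(c(gpos[1], gpos[length(gpos)]), nrow = 1)
  }
  m <- transcript_model("rt", "rg", "c1", strand,
                        exons = rbind(c(1L, e1), c(e2_start, e2_end)),
                        cds = cds_iv)
  list(model = m, ref = c(c1 = seq))
}

# minimal inosine_sites-like data.frame for stats tests
make_sites <- function(transcript_id, region = "cds", efficiency = 0.5,
                       ad_ref = 5L, ad_alt = 5L) {
  n <- length(transcript_id)
  if (n == 0) return(inoscan:::empty_sites())
  transcript_id <- as.character(transcript_id)
  structure(
    data.frame(contig = "c1", gpos = seq_len(n),
               transcript_id = transcript_id,
               transcript_pos = seq_len(n),
               region = rep_len(region, n), ref = "A", alt = "G",
               ad_ref = rep_len(as.integer(ad_ref), n),
               ad_alt = rep_len(as.integer(ad_alt), n),
               efficiency = rep_len(efficiency, n),
               sample_id = "s1", stringsAsFactors = FALSE),
    class = c("inosine_sites", "data.frame")
  )
}

# minimal codon-context table
make_contexts <- function(codon_ref, codon_pos, efficiency = 0.5,
                          ad_ref = 5L, ad_alt = 5L) {
  n <- max(length(codon_ref), length(codon_pos))
  if (n == 0) {
    return(data.frame(contig = character(), gpos = integer(),
                      transcript_id = character(), transcript_pos = integer(),
                      ad_ref = integer(), ad_alt = integer(),
                      efficiency = numeric(), cds_pos = integer(),
                      codon_ref = character(), codon_alt = character(),
                      codon_pos = integer(), aa_ref = character(),
                      aa_alt = character(), consequence = character(),
                      stringsAsFactors = FALSE))
  }
  codon_ref <- rep_len(codon_ref, n)
  codon_pos <- rep_len(codon_pos, n)
  codon_alt <- codon_ref
  for (i in seq_len(n)) {
    substring(codon_alt[i], codon_pos[i], codon_pos[i]) <- "G"
  }
  code <- genetic_code()
  data.frame(
    contig = "c1", gpos = seq_len(n), transcript_id = paste0("t", seq_len(n)),
    transcript_pos = seq_len(n),
    ad_ref = rep_len(as.integer(ad_ref), n),
    ad_alt = rep_len(as.integer(ad_alt), n),
    efficiency = rep_len(efficiency, n),
    cds_pos = seq_len(n), codon_ref = codon_ref, codon_alt = codon_alt,
    codon_pos = codon_pos,
    aa_ref = unname(code[codon_ref]), aa_alt = unname(code[codon_alt]),
    consequence = classify_consequence(codon_ref, codon_alt),
    stringsAsFactors = FALSE
  )
}
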