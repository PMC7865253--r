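---
title: "Detecting and characterising A-to-I RNA editing from variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising A-to-I RNA editing from variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inoscan)
```

## The measurement model

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Sequencing chemistry reads inosine as guanosine, so an edited position
appears in aligned RNA-seq reads as an A-to-G mismatch against the
genome (on the transcribed strand). `inoscan` starts *after* variant
calling: its input is a VCF of RNA–DNA mismatches with per-allele read
depths, and its job is to decide which records are credible editing
sites and to characterise them.

The identification rules, applied in `call_inosine_sites()`:

* **Known-SNP exclusion.** A genomic A/G polymorphism is
  indistinguishable from an edit in RNA reads, so positions present in
  a SNP blacklist are removed first. Allele balance is *not* used as a
  genotype filter — a site with zero reference reads (efficiency 1.0)
  is retained, because in this design the blacklist, not allelic
  fraction, carries the genotype information; near-complete editing is
  a real phenomenon in ribosome-associated RNA.
* **Sense orientation.** Editing is defined on the transcribed strand.
  The `dialect` flag says how the caller reported alleles: `"sense"`
  (default) means alleles are already transcript-oriented; `"genomic"`
  means minus-strand variants must be complemented (a genomic T>C on a
  minus-strand gene is a sense A>G). Only sense A>G pairs survive.
* **AD > 0.** At least one read must carry the G allele
  (`min_ad_alt = 1`). We interpret the allelic-depth filter as
  *alternate*-allele depth: total depth is positive at any called site,
  which would make the filter vacuous.
* **TPM ≥ 1.** The host transcript must be expressed; `tpm_min = 1`
  (transcripts per million) is the conventional reporting floor. When a
  spike-in is configured (e.g. an mCherry control at a known nominal
  TPM), the table is rescaled by `nominal / observed` spike TPM before
  thresholding, and the spike row is dropped.

Editing efficiency is the allelic fraction
`AD_alt / (AD_ref + AD_alt)`, the standard editing index. It sits in
(0, 1] for every reported site because of the AD filter. Under a
binomial read-sampling model at depth `d`, the per-site estimator has
standard error `sqrt(e(1-e)/d)`, which is why per-codon summaries
average over sites rather than trusting single observations.

A variant that overlaps several transcript models yields one annotated
row per qualifying transcript; *unique modified transcripts* are
counted downstream (`count_modified_transcripts()`), where a transcript
counts once if it carries at least one site. The modified proportion
uses expressed transcripts (TPM ≥ 1) as its denominator. For
between-group comparisons, `restrict_to_common()` limits the analysis
to transcripts expressed in every sample, so expression differences are
not mistaken for editing differences.

## Coordinates and gene models

External formats keep their native conventions (GFF3 and VCF are
1-based, closed). Internally we also work in 1-based closed
coordinates — the native convention of R and Bioconductor interval
code — rather than converting to 0-based half-open arithmetic and back;
all public outputs are 1-based. `transcript_model` objects hold sorted,
non-overlapping exons and CDS intervals contained in exons; UTRs are
derived as exonic-minus-CDS and assigned 5′/3′ by strand. Each genomic
position inside a transcript span receives exactly one region label
(`five_prime_utr`, `cds`, `intron`, `three_prime_utr`, or
`noncoding_exon` for transcripts without CDS); the partition property
is tested exhaustively on toy models.

Degenerate inputs are handled conservatively:

* a transcript whose CDS length is not a multiple of 3 is kept for
  region annotation but flagged incomplete and excluded from all
  codon-level analyses (avoids frame-shift artefacts);
* a codon containing an `N` base has undefined context, so the site is
  dropped from codon analyses only;
* mitochondrial contigs (`MT`/`chrM`) are excluded from codon analyses
  with a warning, because they use a different genetic code (only the
  standard NCBI table 1 is implemented);
* GTF input is accepted and normalised to the same transcript model;
  GFF3 is the reference dialect.

## Codon context and consequence

`codon_context()` assembles the codon containing a CDS site from the
*spliced* CDS sequence, so codons spanning exon junctions are correct
by construction; tests verify equivalence with manual splicing on
random two-exon toys. The within-codon position is
`((cds_offset - 1) mod 3) + 1`; position 3 is the wobble position.

Consequences are classified by double translation under the standard
genetic code: synonymous, nonsynonymous, stop_retained, stop_lost,
stop_gained. `enumerate_edits()` provides the exhaustive table of all
48 single A>G codon edits; it doubles as a test oracle and establishes
that stop gain is impossible for a single sense A>G edit. Stop-altering
events are classified but excluded from the downstream codon
statistics, which therefore operate over the 34 adenosine-containing
non-stop codons.

**Isoform aggregation.** Counting an edited codon once per isoform
would multiply-count genes with many transcripts. By default codon
analyses use one *canonical* transcript per gene — the longest complete
CDS, ties broken by lexicographically smallest transcript id — with
`isoform = "all"` available when per-isoform rows are wanted. This is a
design choice; source pipelines built on external consequence
predictors do not document their aggregation, and one-per-gene is the
option that keeps per-codon counts interpretable.

## Statistics

* **Wobble enrichment** (`wobble_enrichment_test()`): Pearson
  chi-square of observed codon-position counts (df 2), without
  continuity correction. The default null in the pipeline is
  *adenosine availability*: expected proportions equal the fraction of
  adenosines at codon positions 1–3 across the expressed CDSs
  (`codon_position_availability()`), since editing opportunities are
  not uniform across positions. A uniform-1/3 null is available by
  omitting the availability argument; the pipeline reports both. A zero
  expected cell raises an error advising pooling rather than silently
  returning an unstable statistic.
* **Per-codon efficiency** (`per_codon_efficiency()`): the default is
  the unweighted mean of per-site efficiencies within each
  (codon, position) class, treating sites as the unit of observation; a
  read-pooled ratio `sum(AD_alt)/sum(AD_total)` is available via
  `method = "pooled"` (it weights deep sites more). Classes are
  labelled with the edited position capitalised, e.g. `aAa`.
* **Efficiency–abundance correlation**: Pearson `r` between
  per-transcript mean efficiency and TPM, two-sided p-value, requiring
  at least three transcripts; zero variance yields an explicit
  undefined marker rather than NaN propagation.
* **Group comparisons** (`compare_groups()`): one-way ANOVA across
  genotype groups, two-way ANOVA for genotype × category cell designs
  (interaction included only when cells are replicated), and Pearson
  chi-square (no continuity correction) for proportion designs. Group
  means are reported ± SEM; a warning flags SEM computed over n = 2
  replicates, which is common in these designs but unstable.
* **Multiple testing**: none is applied by default — tests report raw
  p-values, matching how such figure-level statistics are customarily
  reported; users can adjust afterwards with `p.adjust()`.

## The synthetic-data generator

`simulate_dataset()` exists so every stage of the pipeline can be
exercised and validated without any download. It generates random
multi-exon genes (one contig per gene, both strands, CDS length a
multiple of 3 by construction), plants edits on sense-strand
adenosines, and emits standards-compliant FASTA, GFF3, VCF (with `AD`),
blacklist, abundance table and a planted-truth table. Key defaults and
why:

| parameter | default | rationale |
|---|---|---|
| per-site efficiency | Beta(8, 8), mean 0.5 | total-RNA editing is roughly half-edited per site; a fixed value or other Beta shapes model e.g. near-complete editing in ribosome-associated RNA |
| `wobble_bias` | (0.2, 0.2, 0.6) | a clear but not degenerate wobble-position excess |
| `region_mix` | 5% 5′ UTR, 60% CDS, 5% intron, 30% 3′ UTR | the CDS/3′ UTR-dominated pattern seen in oocyte data |
| `read_depth` | 50 | typical exonic depth at reportable sites; `AD_alt ~ Binomial(depth, efficiency)` |
| `fraction_transcripts_modified` | 0.5 | makes the modified proportion itself a planted, recoverable quantity |
| `fraction_below_tpm1` | 0.25 | TPMs must straddle the reporting threshold for the TPM filter to be exercised |
| `snp_rate` | 0.05 | decoy SNPs are emitted in the VCF *and* listed in the blacklist, exercising the SNP filter |
| `spike_in` | mCherry at nominal TPM 100 | exercises spike normalisation; `observed_factor` scales the observed row |
| `dialect` | sense | matches callers that report transcript-oriented alleles; `genomic` emission writes T>C for minus-strand sites and exercises the orientation logic both ways |

Everything is deterministic under `seed`: identical configs produce
byte-identical files (the run manifest is the one output that varies,
as it records wall-clock stage timings). Sites with `AD_alt = 0` are
deliberately emitted so the AD filter has something to remove, and the
end-to-end property — called sites equal planted truth restricted to
non-decoy, `AD_alt ≥ 1`, host TPM ≥ 1 — is asserted as exact set
equality in the test suite.

**What the generator does not emulate**: sequencing or alignment error
(no spurious mismatches beyond the planted decoys), depth–abundance
coupling (depth is drawn independently of TPM; the analysis never uses
that coupling), isoform complexity (one transcript per gene by
default), hyper-edited clusters, and any relationship between editing
and transcript decay. Passing recovery tests therefore demonstrates
that the *computational* rules are implemented exactly, not that the
pipeline is robust to caller artefacts in real data — on real VCFs the
quality of upstream alignment, duplicate marking and variant filtering
still dominates.

## Problem sizes and tolerances

The default simulation uses 60 genes and 300 planted sites (plus 5%
decoys), which gives a few hundred CDS contexts — enough for every
recovery check while keeping a full test run around a minute. Recovery
tolerances follow the relevant sampling distributions: per-codon-class
efficiency at depth 100 with 50 sites/class is checked to ±0.03 (about
4 binomial standard errors); planted wobble bias (0.2, 0.2, 0.6) at
n = 300 must reject the uniform null at p < 0.05 in ≥ 99/100 seeded
replicates; a planted efficiency–abundance correlation of 0.5 at
n = 200 must land within ±0.15 (several times the asymptotic standard
error of r) in ≥ 95/100 replicates. Position frequencies must sum to 1
within 1e-12; counting statistics must conserve totals exactly.

## Known limitations

* Consequence classification covers single A>G substitutions only — no
  multi-nucleotide or neighbouring-edit interactions.
* Only the standard genetic code is supported; mitochondrial
  transcripts are excluded from codon analyses.
* No deleteriousness prediction (SIFT-style) — that requires external
  conservation models and is out of scope.
* The caller trusts the upstream VCF: it performs no realignment,
  quality filtering, or error modelling.
* `restrict_to_common()` intersects on transcript identity; it does
  not attempt any cross-sample isoform matching beyond ids.
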