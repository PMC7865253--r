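# inoscan

Detection and characterisation of inosine (A-to-I) RNA editing sites
from RNA-seq variant calls.

## The problem

Adenosine deaminases (ADARs) convert adenosines in double-stranded RNA
into inosine, which reverse transcriptases and ribosomes read as
guanosine. Inosine therefore shows up in RNA-seq data as an **A-to-G
mismatch** between reads and the reference genome. Identifying these
sites, and summarising where in transcripts they fall and how
efficiently each position is edited, is a standard transcriptome-wide
analysis in studies of RNA modification — for example in oocyte
maturation, where editing interacts with maternal mRNA decay.

`inoscan` implements the post-variant-calling half of that analysis for
R users. It consumes a VCF of RNA–DNA mismatches with allelic depths
(`AD`), a reference FASTA, gene models (GFF3/GTF) and a transcript
abundance table (TPM), and applies the standard reporting rules:

1. exclude known SNP positions (blacklist);
2. orient alleles to the transcribed strand (gene-model strand) and
   keep only **sense A>G** mismatches;
3. require alternate-allele depth AD > 0;
4. require the host transcript to be expressed at **TPM ≥ 1**
   (optionally after spike-in normalisation, e.g. mCherry).

Each passing site is annotated with its transcript region (5′ UTR, CDS,
intron, 3′ UTR), its codon context (junction-spanning codons are
assembled from the spliced CDS), and its **editing efficiency**

```
efficiency = AD_alt / (AD_ref + AD_alt)
```

the usual allelic-fraction editing index. Downstream statistics cover
unique modified-transcript counts, the modified proportion of the
expressed transcriptome, sites-per-transcript histograms, per-region
and per-codon distributions, codon **wobble-position** (position 3)
enrichment via Pearson chi-square, per-codon mean efficiency, the
Pearson correlation between per-transcript efficiency and abundance,
and one-/two-way ANOVA and chi-square group comparisons.

A consequence classifier re-derives the synonymous / nonsynonymous /
stop-altering categories from the standard genetic code. A useful
analytic fact the package exposes: of the 64 codons, exactly **34**
non-stop codons contain an adenosine, there are **48** possible single
A>G codon edits, and their consequences tally to 13 synonymous, 31
nonsynonymous, 2 stop-retained, 2 stop-lost and 0 stop-gained — no
single sense A>G edit can create a stop codon.

The package also ships a synthetic-data generator
(`simulate_dataset()`) that emits a complete toy dataset (FASTA + GFF3
+ VCF + blacklist + abundance table + planted truth), so the entire
pipeline can be exercised and validated end to end without any
external data.

## Worked example

```r
library(inoscan)

run <- run_all(pipeline_config(simulate = sim_config(seed = 42)),
               outdir = "demo")
print(run)
```

```
<inosine_run> demo
<editing_summary> sample sample1
  235 sites on 24 modified transcripts / 45 expressed (53.3%)
  region counts: five_prime_utr=7, cds=157, intron=8, three_prime_utr=63, noncoding_exon=0
  codon position frequencies: 0.257 / 0.186 / 0.557 (wobble)
  mean editing efficiency: 0.495
```

Reading the output: of 315 simulated variant records, 235 survive the
SNP / A>G / AD / TPM filters; they fall on 24 of the 45 transcripts
expressed at TPM ≥ 1 (53.3% modified — the generator plants edits on
half the transcripts). Most sites are in the CDS and 3′ UTR, the
wobble position carries 55.7% of CDS edits (the generator's planted
bias is 60%), and the mean allelic-fraction efficiency is 0.495
against a planted mean of 0.5. The wobble enrichment test against the
adenosine-availability null:

```r
print(run$tests$wobble_vs_availability)
```

```
Chi-square = 31.6 (df 2), p = 1.377e-07
  position observed expected
1        1       36 46.68446
2        2       26 46.23070
3        3       78 47.08484
```

`run_all()` writes one TSV per analysis (`sites.tsv`,
`fig1_counts.tsv` … `fig6_efficiency.tsv`, `stats_tests.tsv`), a
`summary.json` with filter tallies, and a `run_manifest.json` with
config/input/output digests and stage timings. A thin command-line
wrapper lives at `inst/cli/inoscan.R`
(`Rscript inoscan.R run-all --seed 42 --outdir out`).

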