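Package: inoscan
Title: Detection and Characterisation of Inosine (A-to-I) RNA Editing
    Sites from RNA-Seq Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies putative inosine (A-to-I) RNA editing sites from
    RNA-seq variant calls as sense-strand A-to-G mismatches against a
    reference genome, applying known-SNP exclusion, allelic-depth and
    transcript-abundance (TPM) filters. Annotates each site with its
    transcript region (5' UTR, CDS, intron, 3' UTR), codon context and
    coding consequence under the standard genetic code, and computes the
    downstream editing statistics: modified-transcript counts, per-region
    and per-codon distributions, codon wobble-position enrichment tests,
    per-site editing efficiency from allelic depths, and
    efficiency-abundance correlation. Includes a self-contained synthetic
    transcriptome generator (FASTA, GFF3, VCF, abundance table, planted
    truth) so the entire pipeline can be exercised and validated without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
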