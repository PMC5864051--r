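Package: trisex
Title: Sex-Linked Marker Screening and Functional Mapping for Trioecious Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening sex-determination candidate
    genes in trioecious plants such as papaya, where flower sex is governed by
    an X / Y(m) / Y(h) chromosome system with zygote-lethal Y/Y combinations.
    The package simulates sex-typed transcript sets over reference regions,
    maps transcripts to gene models and applies presence-based candidate
    filters, classifies alternative-splicing and amino-acid-change events
    (intron retention, exon skipping, premature-stop truncation), runs
    in-silico marker assays (PCR, restriction digestion, exon-junction RT-PCR,
    and high-resolution-melting genotype clustering), tests progeny
    segregation ratios with chi-squared goodness of fit, and integrates
    per-locus expression, splicing and genotype calls into rule-based flower
    sex-type predictions including a stable-hermaphrodite call.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
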