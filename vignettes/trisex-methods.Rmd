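---
title: "Methods: sex-linked marker screening and functional mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked marker screening and functional mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisex)
```

## The genetic model

Trioecious plants such as papaya carry three flower sex forms on separate
individuals. Sex is controlled by a single sex-chromosome region with three
classes: X (recessive, female), Y^m (dominant, male) and Y^h (dominant,
hermaphrodite). Viable genotypes are XX (female, F), XY^m (male, M) and
XY^h (hermaphrodite, H); every pairing of two Y-class chromosomes is lethal
to the zygote. A hermaphrodite-by-male cross (XY^h x XY^m) therefore
segregates F : H : M at 1:1:1 after lethality filtering, and markers that
cannot resolve all three alleles collapse classes: a marker with an
X-specific allele separates F from a pooled M+H class (1:2), one with a
Y^m-specific allele separates M from F+H (2:1).

Hermaphrodites are agronomically preferred but developmentally unstable:
under environmental stress they produce female-sterile flowers (HM, the
carpel whorl lost) or carpellate flowers (HF, stamens converted toward
carpels). The package implements a screening pipeline that goes from
sex-typed transcripts mapped onto reference regions, through
splicing/protein-change classification and in-silico marker assays, to
segregation tests and a rule-based "functional map" that calls the flower
sex type and hermaphrodite stability from three loci (`CpSERK`, `CpSVPL`,
`CpCAF1AL`) per floral whorl.

## The synthetic-data generator

`generate_dataset()` simulates every input the pipeline consumes, and
records every planted difference in a truth ledger so the classifier
modules can be scored exactly.

* **Structure.** Each of the (by default 3) reference regions represents
  one chromosome class; each carries multi-exon genes (3-6 exons of
  120-300 bp, introns of 80-150 bp with GT..AG ends). The coding sequence
  starts at ATG, contains no internal stop, ends with TAA, and is flanked
  by 30-bp untranslated ends inside the terminal exons, so every intron
  falls inside the CDS and the CDS length is a codon multiple on the
  unmutated haplotype.
* **Haplotypes.** Each gene has X, Y^m and Y^h haplotypes. F transcripts
  carry the X haplotype, M the Y^m, and H (with the abnormal classes HM and
  HF) the Y^h. Per haplotype the generator plants, independently:
  a non-synonymous substitution (probability 0.3), a premature stop
  (codon rewritten to TAA in the middle third of the CDS), an intron
  retention and an exon skip (each at the configured per-event rate,
  default 0.2). A skipped exon is never adjacent to a retained intron on
  the same haplotype, keeping splice forms coherent.
* **Markers.** One gene per marker class carries a diagnostic SNP at the
  third position of a glycine codon (GGN), so marker SNPs are synonymous
  and do not perturb protein-based typing: the three-sex marker has three
  distinct alleles, the female-type marker an X-specific allele, the
  male-type marker a Y^m-specific allele. Allele melting temperatures are
  spaced by `tm_spacing` (default 1 degree C).
* **Expression.** Baselines are log-normal (meanlog 3, sdlog 0.5, linear
  arbitrary units) with multiplicative log-normal noise; an absent
  transcript has expression 0. Where an elevated level is planted (the
  flower-cohort loci) it is an 8-fold multiplier, so HIGH/LOW calls at the
  2x / 0.5x thresholds are unambiguous; the source study reports
  expression only qualitatively, so the effect size is a package choice.
* **Progeny.** Y/Y lethality is implemented by rejection sampling
  (lethal draws are redrawn), which reproduces the renormalized
  distribution while keeping the audit trail simple.
* **Determinism.** One root seed; each component derives its own
  sub-stream, so adding a component does not perturb the others, and the
  same configuration is byte-identical across runs.

What the generator does *not* emulate: read-level sequencing, assembly
artefacts, multiple isoforms per sex type (one representative transcript
each, as with assembled contigs), paralogy, and real reference sequences.
Passing tests therefore demonstrate correctness of the analysis logic on
clean, fully-audited inputs, not robustness to assembly noise.

## Transcript mapping and the candidate screen

`map_transcripts()` is a desk-scale seed-and-extend mapper: a transcript is
a candidate for a gene when the two share an exact 15-mer; candidates are
aligned globally with affine gaps (match 2, mismatch -3, open -6,
extend -1) against the gene's *genomic* span, so a normally spliced
transcript aligns with intron-sized deletions and an intron-retaining
transcript stays fully covered. Identity is computed over aligned
(gap-free) columns and coverage as the fraction of transcript bases aligned
to reference bases; the default thresholds (identity 0.95, coverage 0.90)
cleanly separate same-gene variants from cross-gene noise in the simulated
regime. Each transcript is assigned to at most one best gene by
identity x coverage, with deterministic tie-breaks (lowest reference id,
then lowest gene coordinate), and transcripts are processed in sorted order
so results do not depend on input order.

`build_presence_table()` ORs presence over each sex type's transcripts and
bins genes by the number of sex types (k = 1, 2, 3). The two candidate
filters are `NOT_F_BUT_MH` (no expression in females, expression in males
and hermaphrodites) and `TWO_OR_THREE_SEXES`. The published gene counts at
this step depend on the study's own dataset; here they are structural
(two nested filters checked against the ledger), not target numbers.

## Splicing and protein-change classification

`align_to_model()` aligns a transcript to the spliced model sequence and
parses the alignment into insertions, deletions and substitutions. Two
numerical details matter:

* **Indel-placement ambiguity.** Where flanking bases repeat, gap placement
  is not unique; every equivalent placement is enumerated and the one
  closest to an annotated splice site is chosen (ties toward the annotated
  site), with +/-2 bp slack on position and length when matching an
  insertion to an intron (retention) or a deletion to an exon (skip).
* **Split alignments.** A substitution close to a splice junction can make
  the optimal alignment split one biological indel into two gap blocks
  bridged by a few opportunistically matched columns. Runs of same-type
  indels separated by at most 10 aligned columns are therefore also tested
  as a single merged event (net length summed). Without this, roughly one
  gene in fifty is misclassified in simulation.

`translate_cds()` locates the annotated CDS start on the transcript through
the alignment and translates in the standard code to the first stop codon;
a stop before the annotated stop is a truncation, and a transcript CDS
whose aligned length is not a codon multiple is flagged as a frameshift.
Truncation is defined by first-stop logic regardless of whether material is
missing N- or C-terminally; both are reported.

Genes expressed in at least two of F, M, H are sorted into four categories
with the precedence EXON_JUMP > INTRON_JUMP > AA_SHORT > NO_CHANGE (exon
skipping, intron retention, premature-stop truncation, no protein change),
which makes the four categories a partition; substitution-only genes are
NO_CHANGE but can still differ in protein for the sex-grouping types:
TYPE_1 (two sex types expressed, proteins differ), TYPE_2 (all three
expressed, all proteins differ), TYPE_3 (all three expressed, exactly one
identical pair). Counting is per gene (one representative transcript per
sex type). Category calls are invariant to the order in which sex types
are compared.

## In-silico marker assays

* **PCR** uses exact primer matching (the assays modelled are
  presence/absence; mismatch tolerance would add knobs without changing
  the logic). All forward/reverse-complement pairings up to 5 kb are
  returned, shortest first; an absent binding site returns no product.
* **Digestion** implements NdeI (CA^TATG) and SpeI (A^CTAGT) with the cut
  offsets of their standard definitions; the enzyme table is extensible.
  Fragments always partition the amplicon.
* **Junction RT-PCR** designs, for each exon-exon junction, a forward
  primer spanning the junction (10 bases each side) and a reverse primer
  inside the downstream exon; retention of the intron abolishes the
  forward site and hence the product, while unaffected junctions yield a
  fixed model-predicted length (70 bp with the defaults). Note that with
  exact matching a SNP under a primer footprint also abolishes a product
  - real assays share this failure mode.
* **Melting curves** use a two-state logistic proxy, not nearest-neighbour
  thermodynamics: a homozygote melts as `1/(1 + exp((T - Tm)/s))` and a
  heterozygote is the equal mixture of its two homoduplex curves and two
  heteroduplex curves displaced 1 degree C lower. The clustering analysis
  is shape-based, so a thermodynamic Tm model would add realism without
  changing what is being tested.
* **Normalization** fits linear baselines in pre- and post-melt windows
  and rescales to the fraction between them. The default windows span
  7 degrees C (65-72 and 83-90 on the default 65-90 grid): with narrow
  2-degree end windows, baseline extrapolation amplifies pointwise
  fluorescence noise several-fold at mid-curve temperatures and swamps the
  genotype signal. A degenerate (flat) curve, where the baselines
  coincide, is an error.
* **Clustering** seeds one centroid per reference genotype (known-sex
  samples), smooths curves with a 5-point moving average, and assigns each
  sample to the nearest centroid by maximum absolute difference, or to a
  singleton cluster when no centroid is nearer than `d = 0.05` normalized
  units. Per-sex concordance is the share of known-sex samples assigned to
  the cluster seeded by their own sex; at a female-type marker the M and H
  references seed the same cluster and downstream counting pools them. The
  published per-sample correlation percentages come from proprietary
  software on real samples and are not reproduction targets; the package's
  property is recovery of planted genotypes (100% of 200 samples at
  1 degree C allele spacing and noise SD 0.01).

## Segregation testing

`chi_square_gof()` is Pearson's statistic without continuity correction;
the uncorrected statistic reproduces the reproducible published values
(4.69, 0.02, 1.69, 0.42, 0.16, 0.67 for the blind panels) to the printed
precision, which is why no Yates correction is applied. Critical values
3.841 (df 1) and 5.991 (df 2) are hard-coded, the general case uses the
chi-squared quantile; the statistic is displayed rounded half-up to two
decimals alongside full precision. Two published rows are knowingly
excluded: a 1:1:1 row printing 0.01 where the uncorrected statistic on the
printed counts is 0.02 (0.025 unrounded), and a 2:1 row printing 4.08 that
is not reproducible from its printed counts under either 2:1 or 1:2; the
implementation is not tuned toward either. Calibration is checked by
simulation: under the true multinomial null at n = 96 the rejection rate at
the 5% critical value is 0.05 +/- 0.01 over 10,000 replicates.

## The functional map

Each sample's locus profile is the triple (expression class, splicing
flag, genotype class) at `CpSERK`, `CpSVPL` and `CpCAF1AL`. Expression is
classified against the median of the housekeeping-normalized panel (HIGH
at >= 2x, LOW at <= 0.5x). The panel pooled across loci is used in the
cohort pipeline: its median sits at the unchanged-expression baseline even
at loci where no class is at baseline (at `CpSVPL` every class is either
elevated or reduced, so a per-locus median would fall inside one of the
groups). The splicing flag is AS when any junction assay loses its product
or shifts by more than 5 bp.

The rule table (data, not code) maps the five canonical profiles, in locus
order `CpSERK`/`CpSVPL`/`CpCAF1AL`, to M, H, HM, HF and the fourth-whorl
female profile; anything else is UNKNOWN. `CpSERK` expression shows no
variance between classes, so only its splicing flag discriminates (encoded
as class NOVAR). Rule matching uses the genotype observed at `CpSVPL`,
whose three-sex marker resolves all three chromosome classes. The
"partial cDNA" feature of the fourth-whorl female profile and the
X-/Y-specific expression marks are recorded as annotations, not rules -
their operational definitions are not specified. The
stable-hermaphrodite call is defined only for profiles predicted H: stable
means no female (XX) genotype at `CpSERK`, the XY^h genotype at `CpSVPL`,
and no male (XY^m) genotype at `CpCAF1AL`.

The cohort generator draws flower classes at proportions
F 0.30 / M 0.25 / H 0.25 / HM 0.10 / HF 0.10 (abnormal hermaphrodites are
the minority in field populations) and assays F flowers in the fourth
whorl, the other classes in the third. On a noise-free cohort the calls
reproduce the planted classes exactly; with log-scale expression noise of
SD 0.25 the accuracy stays above 0.95 (the binding constraint is the NOVAR
band, about 2.8 SD wide on each side).

## Problem sizes and runtime choices

The test suite and the acceptance script use: 51-gene datasets (3
references x 17 genes) for classification recovery, 10,000 replicates for
the calibration check, 10,000 fuzz cases for the PCR/digestion oracles,
200-sample panels for melt clustering and flower-type calling, and 300,000
progeny for the segregation law-of-large-numbers check. These sizes give
sub-minute module runtimes while leaving the stochastic checks enough
resolution for the stated tolerances.

## Worked example

```{r example}
cfg <- sim_config(seed = 1, genes_per_reference = 4)
bundle <- generate_dataset(cfg)
bundle

cls <- run_as_classification(bundle$transcripts, bundle$models,
                             bundle$references)
table(cls$category, useNA = "ifany")

segregation_table(bundle$progeny, bundle$markers)

functional_map_table()
```

## Known limitations

* One representative transcript per gene per sex type; no isoform
  mixtures or quantitative splicing (PSI).
* Exact-match PCR: primer-binding SNPs abolish products, which the
  splicing flag then reports as AS - as in real presence/absence assays.
* The melt model is a logistic proxy; allele melting temperatures are
  generator inputs, not sequence predictions.
* Minus-strand gene models are supported in sequence extraction but the
  generator emits plus-strand genes; strand handling beyond reverse
  complementation is untested territory.
* The rule table encodes one species' locus triple; other loci can be
  loaded, but the stable-hermaphrodite rule is specific to the three
  canonical loci.
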