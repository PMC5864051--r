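# trisex

Sex-linked marker screening and functional mapping for trioecious plants.

## The problem

Papaya and other trioecious crops carry three flower sex forms — female
(XX), male (XY<sup>m</sup>) and hermaphrodite (XY<sup>h</sup>) — governed by
a single sex-chromosome region in which every pairing of two Y-class
chromosomes is lethal to the zygote. Growers prefer hermaphrodites, but
hermaphrodite flowers are developmentally unstable, reverting to
female-sterile (HM) or carpellate (HF) forms. Breeding stable hermaphrodites
needs molecular markers that (i) tag the sex chromosome classes and (ii)
report the expression and splicing state of the sex-related loci in the
floral whorls.

`trisex` implements this screening pipeline end to end, at desk scale, for
method development and teaching:

* **synthio** — a seeded generator of sex-typed transcript sets over
  reference regions, with planted sex-specific SNPs, splicing variants
  (intron retention, exon skipping, premature stops), expression effects,
  and progeny panels from a hermaphrodite × male cross with Y/Y lethality;
  every planted event is recorded in a truth ledger.
* **bacmap** — transcript-to-gene mapping (seed-and-extend, affine-gap
  alignment) and the presence-based candidate filters.
* **asclass** — splice/coding-event calling against the gene model and the
  four-category classification (exon jump, intron jump, AA short, no
  change) plus the three sex-grouping types.
* **markerlab** — in-silico PCR, restriction digestion (NdeI/SpeI),
  exon-junction RT-PCR, and high-resolution-melting (HRM) curve
  simulation, normalization and genotype clustering.
* **segtest** — chi-squared goodness of fit of progeny sex classes against
  the 1:1:1, 1:2 and 2:1 ratios induced by the marker class, with pooling
  (M+H for female-type markers, F+H for male-type markers).
* **wholemap** — integration of per-locus (expression class, splicing
  flag, genotype class) into flower sex-type calls and the
  stable-hermaphrodite rule.

The central statistic is Pearson's goodness of fit without continuity
correction, `chi2 = sum((O_i - E_i)^2 / E_i)` with
`E_i = sum(O) * r_i / sum(r)`, judged at the 5% critical value (3.841 for
df 1, 5.991 for df 2).

## Worked example

```r
library(trisex)

cfg <- sim_config(seed = 1, genes_per_reference = 4)
bundle <- generate_dataset(cfg)
bundle
#> Synthetic screening dataset
#>   references : 3
#>   genes      : 12
#>   transcripts: 144 (134 present)
#>   ledger     : 42 planted events
#>   markers    : THREE_SEX, FEMALE_TYPE, MALE_TYPE
#>   progeny    : 96 samples

cls <- run_as_classification(bundle$transcripts, bundle$models,
                             bundle$references)
table(cls$category, useNA = "ifany")
#>    AA_SHORT   EXON_JUMP INTRON_JUMP   NO_CHANGE        <NA>
#>           1           4           4           2           1
```

One gene is `NA` because only one sex type expresses it, so there is
nothing to compare; the others are sorted by the precedence exon jump >
intron jump > AA short > no change. The blind 96-sample progeny panel
segregates as its marker classes predict:

```r
segregation_table(bundle$progeny, bundle$markers)
#>             marker       class       observed ratio chi2 df significant
#> 1   g001_THREE_SEX   THREE_SEX F=33,H=26,M=37 1:1:1 1.94  2       FALSE
#> 2 g005_FEMALE_TYPE FEMALE_TYPE    F=33,M+H=63   1:2 0.05  1       FALSE
#> 3   g009_MALE_TYPE   MALE_TYPE    F+H=59,M=37   2:1 1.17  1       FALSE
```

None of the tests rejects the expected ratio, i.e. the markers tag the sex
classes faithfully. A panel that does deviate is flagged; for example an
observed 42 females versus 54 pooled males-plus-hermaphrodites against 1:2:

```r
chi_square_gof(pool_counts(c(F = 42, H = 30, M = 24), "FEMALE_TYPE"))
#> chi-squared segregation test (ratio 1:2)
#>   observed: F=42, M+H=54
#>   chi2 = 4.69 (df = 1), p = 0.03038 *
```

The functional map that the flower-type caller applies (one row per flower
class; each cell is expression class / splicing flag at that locus):

```r
functional_map_table()
#>      flower_type  whorl          CpSERK         CpSVPL       CpCAF1AL genotype
#> 1              M  third novar/no AS-seq high/no AS-seq high/no AS-seq      XYm
#> 2              H  third novar/no AS-seq  low/no AS-seq high/no AS-seq      XYh
#> 3             HM  third    novar/AS-seq high/no AS-seq     low/AS-seq      XYh
#> 4             HF  third    novar/AS-seq  low/no AS-seq     low/AS-seq      XYh
#> 5 F_fourth_whorl fourth    novar/AS-seq  low/no AS-seq     low/AS-seq       XX
```

See `vignettes/trisex-methods.Rmd` for the full account of the models,
parameter choices and limitations, and `inst/cli/trisex.R` for a thin
command-line wrapper (`simulate`, `segtest`, `run-all`).

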