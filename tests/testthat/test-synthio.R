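test_that("configuration validation rejects contradictory settings", {
  expect_error(sim_config(genes_per_reference = 0), "counts")
  expect_error(sim_config(exon_len = c(300, 120)), "ranges")
  expect_error(sim_config(exon_len = c(20, 40)), "60 bp")
  expect_error(sim_config(as_event_rates = c(INTRON_RETENTION = 1.4,
                                             EXON_SKIP = 0, PREMATURE_STOP = 0)),
               "probabilities")
  expect_error(sim_config(snp_sex_classes = "BLUE"), "marker class")
})

test_that("the same seed yields byte-identical bundles and files", {
  cfg <- sim_config(seed = 5, genes_per_reference = 2)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(b1, d1)
  write_dataset(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("zero event rates produce SNP-only haplotypes", {
  cfg <- sim_config(seed = 8, genes_per_reference = 3,
                    as_event_rates = c(INTRON_RETENTION = 0, EXON_SKIP = 0,
                                       PREMATURE_STOP = 0))
  b <- generate_dataset(cfg)
  expect_false(any(b$ledger$event_type %in%
                   c("INTRON_RETENTION", "EXON_SKIP", "PREMATURE_STOP")))
  # all sex types of a gene then share the spliced length (SNPs only)
  tx <- b$transcripts[b$transcripts$present, ]
  lens <- tapply(nchar(tx$sequence), tx$gene_id, function(x) length(unique(x)))
  expect_true(all(lens == 1L))
})

test_that("transcript record count matches the presence ledger", {
  b <- small_bundle()
  expected <- 0L
  for (gid in b$truth$gene_id) {
    tr <- b$truth[b$truth$gene_id == gid, ]
    pres <- c(F = tr$present_F, M = tr$present_M, H = tr$present_H,
              HM = tr$present_H, HF = tr$present_H)
    expected <- expected +
      sum(vapply(names(pres), function(s)
        if (pres[[s]]) length(trisex:::SEX_WHORLS[[s]]) else 0L, integer(1)))
  }
  expect_identical(sum(b$transcripts$present), expected)
  expect_true(all(b$transcripts$expression[!b$transcripts$present] == 0))
})

test_that("every haplotype transcript is reconstructible from the ledger", {
  b <- small_bundle()
  for (gid in names(b$models)) {
    for (hap in c("X", "Ym", "Yh")) {
      sex <- trisex:::HAPLOTYPE_SEXES[[hap]][1]
      row <- b$transcripts[b$transcripts$gene_id == gid &
                           b$transcripts$sex_type == sex &
                           b$transcripts$whorl == "bud28", ]
      if (!row$present) next
      expect_identical(reconstruct_transcript(b, gid, hap), row$sequence,
                       label = paste(gid, hap))
    }
  }
})

test_that("each marker class plants its diagnostic allele pattern", {
  b <- small_bundle()
  m <- b$markers
  expect_setequal(m$class, c("THREE_SEX", "FEMALE_TYPE", "MALE_TYPE"))
  three <- m[m$class == "THREE_SEX", ]
  expect_length(unique(c(three$allele_X, three$allele_Ym, three$allele_Yh)), 3L)
  fem <- m[m$class == "FEMALE_TYPE", ]
  expect_identical(fem$allele_Ym, fem$allele_Yh)
  expect_false(fem$allele_X == fem$allele_Ym)
  mal <- m[m$class == "MALE_TYPE", ]
  expect_identical(mal$allele_X, mal$allele_Yh)
  expect_false(mal$allele_Ym == mal$allele_X)
})

test_that("progeny generator respects the lethality filter and ratios", {
  big <- generate_progeny(c("XYh", "XYm"), 300000, seed = 123)
  expect_true(all(big$genotype %in% c("XX", "XYm", "XYh")))
  freq <- table(big$phenotype) / nrow(big)
  expect_true(all(abs(freq - 1 / 3) < 0.005))

  fm <- generate_progeny(c("XX", "XYm"), 100, seed = 1)
  expect_setequal(unique(fm$phenotype), c("F", "M"))

  expect_error(generate_progeny(c("XX", "XX"), 10), "no cross possible")
  expect_error(generate_progeny(c("XZ", "XYm"), 10), "parents")
})

test_that("bundle progeny carries marker alleles consistent with genotype", {
  b <- small_bundle()
  m <- b$markers[b$markers$class == "FEMALE_TYPE", ]
  col <- paste0(m$marker, "_alleles")
  al <- c(X = m$allele_X, Ym = m$allele_Ym, Yh = m$allele_Yh)
  hom <- paste0(al[["X"]], "/", al[["X"]])
  xx <- b$progeny[b$progeny$genotype == "XX", col]
  expect_true(all(xx == hom))
  het <- b$progeny[b$progeny$genotype != "XX", col]
  expect_true(all(het != hom))
})
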