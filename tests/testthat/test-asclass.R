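test_that("an exact spliced transcript yields no events", {
  b <- small_bundle()
  gid <- names(b$models)[4]
  model <- b$models[[gid]]
  ref <- b$references[[model$reference_id]]
  ev <- align_to_model(spliced_sequence(model, ref), model, ref)
  expect_identical(nrow(ev), 0L)
})

test_that("planted retentions and skips are recovered at the right index", {
  b <- small_bundle()
  led <- b$ledger
  checked <- 0L
  for (i in which(led$event_type %in% c("INTRON_RETENTION", "EXON_SKIP"))) {
    gid <- led$gene_id[i]
    sex <- strsplit(led$sex_types[i], ",")[[1]][1]
    row <- b$transcripts[b$transcripts$gene_id == gid &
                         b$transcripts$sex_type == sex &
                         b$transcripts$whorl == "bud28", ]
    if (!row$present) next
    model <- b$models[[gid]]
    ev <- align_to_model(row$sequence, model,
                         b$references[[model$reference_id]])
    type <- led$event_type[i]
    hit <- ev[ev$type == type, ]
    expect_identical(nrow(hit), 1L, label = paste(gid, type))
    expect_identical(hit$index, as.integer(led$position[i]),
                     label = paste(gid, type))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("a transcript from an unrelated gene is rejected", {
  b <- small_bundle()
  gids <- names(b$models)
  m1 <- b$models[[gids[1]]]
  m2 <- b$models[[gids[2]]]
  tx2 <- spliced_sequence(m2, b$references[[m2$reference_id]])
  expect_error(align_to_model(tx2, m1, b$references[[m1$reference_id]]),
               "does not match")
})

test_that("translation follows the standard code from the CDS anchor", {
  # one-exon toy gene: 30 nt UTRs around ATG AAA TAG
  ref <- paste0(strrep("C", 30), "ATGAAATAG", strrep("G", 30))
  model <- trisex:::gene_model("toy", "r", data.frame(start = 0, end = 69),
                               cds_start = 30, cds_end = 39)
  tr <- translate_cds(ref, model, ref)
  expect_identical(tr$aa, "MK")
  expect_identical(tr$stop_codon, 3L)
  expect_false(tr$truncated)
  expect_false(tr$frameshift)
})

test_that("planted premature stops are reported as truncations", {
  b <- small_bundle()
  led <- b$ledger[b$ledger$event_type == "PREMATURE_STOP", ]
  expect_gt(nrow(led), 0L)
  for (i in seq_len(nrow(led))) {
    gid <- led$gene_id[i]
    sex <- strsplit(led$sex_types[i], ",")[[1]][1]
    row <- b$transcripts[b$transcripts$gene_id == gid &
                         b$transcripts$sex_type == sex &
                         b$transcripts$whorl == "bud28", ]
    if (!row$present) next
    model <- b$models[[gid]]
    tr <- translate_cds(row$sequence, model,
                        b$references[[model$reference_id]])
    codon <- as.integer(sub(".*codon=", "", led$detail[i]))
    # the planted stop is the earliest stop unless a splice event on the
    # same haplotype truncates upstream of it
    expect_true(tr$truncated, label = paste(gid, sex))
    expect_lte(tr$stop_codon, codon)
  }
})

test_that("a frameshifting indel is flagged", {
  ref <- paste0(strrep("C", 30), "ATGAAACCCTAG", strrep("G", 30))
  model <- trisex:::gene_model("toy", "r", data.frame(start = 0, end = 72),
                               cds_start = 30, cds_end = 42)
  tx <- paste0(strrep("C", 30), "ATGAAACCTAG", strrep("G", 30))  # -1 nt
  tr <- translate_cds(tx, model, ref)
  expect_true(tr$frameshift)
})

test_that("translation agrees with the codon-table oracle on random CDS", {
  set.seed(7)
  for (i in 1:200) {
    nt <- random_dna_chr(3L * sample(5:60, 1L))
    mine <- trisex:::translate_nt(nt)
    oracle <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE))
    expect_identical(mine, oracle)
  }
})

test_that("category precedence is respected and order-invariant", {
  ev <- function(type) data.frame(type = type, index = 1L, pos = 0L,
                                  len = 1L, detail = "")
  none <- data.frame(type = character(0), index = integer(0),
                     pos = integer(0), len = integer(0),
                     detail = character(0))
  g <- list(F = list(events = ev("INTRON_RETENTION"), truncated = FALSE),
            M = list(events = ev("EXON_SKIP"), truncated = TRUE),
            H = list(events = none, truncated = FALSE))
  expect_identical(classify_as_category(g), "EXON_JUMP")
  expect_identical(classify_as_category(rev(g)), "EXON_JUMP")
  g$M$events <- none
  expect_identical(classify_as_category(g), "INTRON_JUMP")
  g$F$events <- none
  expect_identical(classify_as_category(g), "AA_SHORT")
  g$M$truncated <- FALSE
  expect_identical(classify_as_category(g), "NO_CHANGE")
  expect_error(classify_as_category(g["F"]), "fewer than two")
})

test_that("sex-grouping types follow the presence/identity rules", {
  p3 <- c(F = TRUE, M = TRUE, H = TRUE)
  expect_identical(classify_sex_group_type(
    p3, c("F:M" = FALSE, "F:H" = TRUE, "M:H" = FALSE)), "TYPE_3")
  expect_identical(classify_sex_group_type(
    p3, c("F:M" = FALSE, "F:H" = FALSE, "M:H" = FALSE)), "TYPE_2")
  expect_identical(classify_sex_group_type(
    p3, c("F:M" = TRUE, "F:H" = TRUE, "M:H" = TRUE)), "NONE")
  p2 <- c(F = FALSE, M = TRUE, H = TRUE)
  expect_identical(classify_sex_group_type(p2, c("M:H" = FALSE)), "TYPE_1")
  expect_identical(classify_sex_group_type(p2, c("M:H" = TRUE)), "NONE")
  expect_identical(classify_sex_group_type(c(F = TRUE, M = FALSE, H = FALSE),
                                           logical(0)), "NONE")
})

test_that("classification recovers the truth ledger on a small cohort", {
  b <- small_bundle()
  res <- run_as_classification(b$transcripts, b$models, b$references)
  m <- merge(res, b$truth, by = "gene_id")
  cat_ok <- ifelse(is.na(m$category.x) & is.na(m$category.y), TRUE,
                   m$category.x == m$category.y)
  expect_true(all(cat_ok))
  expect_true(all(m$sex_group_type.x == m$sex_group_type.y))
})
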