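test_that("an exact spliced transcript maps with identity and coverage 1", {
  b <- small_bundle()
  gid <- names(b$models)[2]
  model <- b$models[[gid]]
  tx <- data.frame(transcript_id = "t1",
                   sequence = spliced_sequence(model,
                     b$references[[model$reference_id]]))
  hits <- map_transcripts(tx, b$references, b$models)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$gene_id, gid)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
})

test_that("a single SNP yields identity (L-1)/L, matching an edit-distance oracle", {
  b <- small_bundle()
  gid <- names(b$models)[1]
  model <- b$models[[gid]]
  sp <- spliced_sequence(model, b$references[[model$reference_id]])
  mut <- sp
  pos <- nchar(sp) %/% 2L
  old <- substring(mut, pos, pos)
  substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  hits <- map_transcripts(data.frame(transcript_id = "t1", sequence = mut),
                          b$references, b$models)
  expect_identical(hits$gene_id, gid)
  L <- nchar(sp)
  expect_equal(hits$identity, (L - 1) / L, tolerance = 1e-12)
  # brute-force oracle: edit distance between transcript and spliced gene
  expect_identical(as.integer(utils::adist(mut, sp)), 1L)
})

test_that("transcripts of absent genes and empty references are handled", {
  b <- small_bundle()
  set.seed(1)
  alien <- data.frame(transcript_id = "alien",
                      sequence = random_dna_chr(800))
  hits <- map_transcripts(alien, b$references, b$models)
  expect_identical(nrow(hits), 0L)
  expect_error(map_transcripts(alien, character(0), b$models),
               "empty reference set")
  expect_error(map_transcripts(alien, b$references, b$models,
                               min_identity = 0), "thresholds")
})

test_that("presence table on noise-free output equals the ledger truth", {
  b <- small_bundle()
  tx <- bundle_transcripts(b)
  hits <- map_transcripts(tx, b$references, b$models)
  pt <- build_presence_table(hits, b$models,
                             stats::setNames(tx$sex_type, tx$transcript_id))
  expect_identical(pt$gene_id, b$truth$gene_id)
  expect_identical(pt$F, b$truth$present_F)
  expect_identical(pt$M, b$truth$present_M)
  expect_identical(pt$H, b$truth$present_H)
  # k-bin counts partition the genes with at least one hit
  k <- attr(pt, "k_counts")
  expect_identical(sum(k), length(unique(hits$gene_id)))
})

test_that("mapping is invariant to transcript input order", {
  b <- small_bundle()
  tx <- bundle_transcripts(b)
  hits1 <- map_transcripts(tx, b$references, b$models)
  set.seed(42)
  hits2 <- map_transcripts(tx[sample(nrow(tx)), ], b$references, b$models)
  expect_identical(hits1, hits2)
})

test_that("candidate rules match a brute-force scan of the ledger", {
  b <- small_bundle()
  tx <- bundle_transcripts(b)
  hits <- map_transcripts(tx, b$references, b$models)
  pt <- build_presence_table(hits, b$models,
                             stats::setNames(tx$sex_type, tx$transcript_id))
  tr <- b$truth
  expect_setequal(select_candidate_genes(pt, "NOT_F_BUT_MH", b$models),
                  tr$gene_id[!tr$present_F & tr$present_M & tr$present_H])
  expect_setequal(select_candidate_genes(pt, "TWO_OR_THREE_SEXES", b$models),
                  tr$gene_id[tr$n_sexes >= 2])
  # a gene seen only in F is never a candidate
  f_only <- tr$gene_id[tr$present_F & tr$n_sexes == 1]
  for (g in f_only) {
    expect_false(g %in% select_candidate_genes(pt, "NOT_F_BUT_MH", b$models))
    expect_false(g %in% select_candidate_genes(pt, "TWO_OR_THREE_SEXES",
                                               b$models))
  }
  expect_error(select_candidate_genes(pt, "EVERYTHING", b$models),
               "unknown rule")
})

test_that("empty hit list gives an all-absent presence table", {
  b <- small_bundle()
  empty <- map_transcripts(data.frame(transcript_id = character(0),
                                      sequence = character(0)),
                           b$references, b$models)
  pt <- build_presence_table(empty, b$models, character(0))
  expect_true(all(!pt$F & !pt$M & !pt$H))
  expect_identical(unname(attr(pt, "k_counts")), c(0L, 0L, 0L))
})
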