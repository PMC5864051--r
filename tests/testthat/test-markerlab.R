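test_that("in-silico PCR reproduces a hand-computed amplicon", {
  fwd <- "ACGTACGTACGTACGTAA"                 # 18 nt
  rev <- "TTGCATGCATGCATGCAT"                 # 18 nt
  template <- paste0("AAAA", fwd, strrep("C", 10), revcomp_chr(rev), "TTTT")
  amp <- in_silico_pcr(template, fwd, rev)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, 18L + 10L + 18L)
  expect_identical(amp$start, 4L)
  expect_identical(amp$sequence,
                   paste0(fwd, strrep("C", 10), revcomp_chr(rev)))
})

test_that("absent primers yield no product; short primers error", {
  expect_identical(nrow(in_silico_pcr(strrep("A", 100),
                                      "CGCGCGCGCGCGCGCG",
                                      "GCGCGCGCGCGCGCGC")), 0L)
  expect_error(in_silico_pcr("ACGT", "ACGTACGTACGT", "ACGTACGTACGTACGT"),
               "15 nt")
})

test_that("PCR agrees with the naive substring-scan oracle on fuzz cases", {
  set.seed(31)
  for (i in 1:400) {
    fwd <- random_dna_chr(16)
    rev <- random_dna_chr(16)
    template <- random_dna_chr(sample(60:240, 1))
    # plant the primer pair in about half the cases
    if (i %% 2 == 0) {
      insert <- paste0(fwd, random_dna_chr(sample(5:60, 1)), revcomp_chr(rev))
      at <- sample(nchar(template), 1)
      template <- paste0(substring(template, 1, at), insert,
                         substring(template, at + 1))
    }
    mine <- in_silico_pcr(template, fwd, rev)
    oracle <- naive_pcr(template, fwd, rev)
    expect_identical(mine[, c("start", "end", "length")],
                     `rownames<-`(oracle, NULL))
  }
})

test_that("restriction digestion matches the cut-offset arithmetic", {
  amp <- paste0(random_seqs <- strrep("A", 97), "CATATG", strrep("G", 97))
  d <- digest(amp, "NdeI")
  expect_identical(d$fragments, c(99L, 101L))
  expect_identical(sum(d$fragments), nchar(amp))

  no_site <- strrep("AC", 100)
  expect_identical(digest(no_site, "NdeI")$fragments, 200L)

  two <- paste0(strrep("T", 20), "ACTAGT", strrep("T", 30), "ACTAGT",
                strrep("T", 20))
  d2 <- digest(two, "SpeI")
  expect_identical(length(d2$fragments), 3L)
  expect_identical(sum(d2$fragments), nchar(two))
  expect_error(digest(two, "EcoRI"), "unknown enzyme")
})

test_that("digest fragments always sum to the amplicon length (fuzz)", {
  set.seed(17)
  for (i in 1:2000) {
    amp <- random_dna_chr(sample(30:300, 1))
    if (i %% 3 == 0)  # enrich with planted sites
      amp <- paste0(amp, "CATATG", random_dna_chr(20), "ACTAGT")
    for (enz in c("NdeI", "SpeI")) {
      d <- digest(amp, enz)
      expect_identical(sum(d$fragments), nchar(amp))
      expect_identical(d$fragments,
                       as.integer(naive_digest_fragments(
                         amp, trisex:::RESTRICTION_ENZYMES[[enz]]$site,
                         trisex:::RESTRICTION_ENZYMES[[enz]]$cut)))
    }
  }
})

test_that("junction primers detect planted intron retentions", {
  b <- small_bundle()
  led <- b$ledger[b$ledger$event_type == "INTRON_RETENTION", ]
  expect_gt(nrow(led), 0L)
  for (gid in unique(b$ledger$gene_id)) {
    model <- b$models[[gid]]
    ref <- b$references[[model$reference_id]]
    primers <- design_junction_primers(model, ref)
    for (sex in c("F", "M", "H")) {
      row <- b$transcripts[b$transcripts$gene_id == gid &
                           b$transcripts$sex_type == sex &
                           b$transcripts$whorl == "bud28", ]
      if (!row$present) next
      hap <- trisex:::SEX_HAPLOTYPE[[sex]]
      gl <- b$ledger[b$ledger$gene_id == gid & b$ledger$haplotype == hap, ]
      retained <- gl$position[gl$event_type == "INTRON_RETENTION"]
      skipped <- gl$position[gl$event_type == "EXON_SKIP"]
      # skipping exon e destroys junctions e-1 and e; SNPs under a primer
      # footprint also abolish that junction's product
      splice_hit <- c(retained, skipped, skipped - 1L)
      snp_hit <- snp_touched_junctions(b, gid, hap)
      res <- junction_rtpcr(row$sequence, primers)
      for (r in seq_len(nrow(res))) {
        j <- res$junction[r]
        if (j %in% splice_hit) {
          expect_true(is.na(res$observed_len[r]) ||
                      res$observed_len[r] != res$expected_len[r],
                      label = paste(gid, sex, "junction", j))
        } else if (!j %in% snp_hit) {
          expect_identical(res$observed_len[r], res$expected_len[r],
                           label = paste(gid, sex, "junction", j))
        }
      }
    }
  }
})

test_that("melt curves follow the logistic mixture model", {
  tm <- c(A = 77, B = 79)
  hom <- simulate_melt(c("A", "A"), tm, noise_sd = 0, seed = 1)
  expect_equal(hom$fluorescence[hom$temperature == 77], 0.5)
  expect_true(all(diff(hom$fluorescence) < 0))
  het <- simulate_melt(c("A", "B"), tm, s = 0.35, d_tm = 1, noise_sd = 0)
  grid <- het$temperature
  logistic <- function(t0) 1 / (1 + exp((grid - t0) / 0.35))
  oracle <- (logistic(77) + logistic(79) + logistic(76) + logistic(78)) / 4
  expect_equal(het$fluorescence, oracle, tolerance = 1e-12)
  # determinism under seed
  n1 <- simulate_melt(c("A", "B"), tm, noise_sd = 0.02, seed = 9)
  n2 <- simulate_melt(c("A", "B"), tm, noise_sd = 0.02, seed = 9)
  expect_identical(n1, n2)
  expect_error(simulate_melt(c("A", "B"), c(A = 60, B = 79)), "70, 88")
  expect_error(simulate_melt(c("A", "A"), tm, grid = c(70, 69, 68)),
               "ascending")
})

test_that("normalization is idempotent on an ideal curve and affine-invariant", {
  ideal <- simulate_melt(c("A", "A"), c(A = 78), noise_sd = 0)
  n1 <- normalize_melt(ideal)
  inner <- n1$temperature > 72 & n1$temperature < 83
  expect_equal(n1$fluorescence[inner], ideal$fluorescence[inner],
               tolerance = 1e-6)
  scaled <- ideal
  scaled$fluorescence <- 3 * ideal$fluorescence + 2
  n2 <- normalize_melt(scaled)
  expect_equal(n2$fluorescence, n1$fluorescence, tolerance = 1e-6)

  flat <- data.frame(temperature = seq(65, 90, 0.2), fluorescence = 1)
  expect_error(normalize_melt(flat), "degenerate")
  expect_error(normalize_melt(ideal, pre_window = c(65, 65.2)),
               "at least 3 points")
})

test_that("noise-free curves cluster perfectly with 100% concordance", {
  panel <- hrm_panel(n_blind = 30, noise_sd = 0, seed = 3)
  res <- cluster_melt(panel$curves, panel$reference,
                      known_sex = panel$known_sex)
  blind <- res$calls[res$calls$sample_id %in% panel$blind_ids, ]
  expect_true(all(blind$cluster ==
                  panel$blind_genos[match(blind$sample_id, panel$blind_ids)]))
  expect_true(all(res$correlation == 100))
})

test_that("a female-type marker pools M and H into one cluster", {
  # Ym and Yh alleles identical: XYm and XYh melt identically
  tm <- c(X = 77, Y = 78.5)
  alleles <- list(XX = c("X", "X"), XYm = c("X", "Y"), XYh = c("X", "Y"))
  ids <- c(sprintf("f%02d", 1:10), sprintf("m%02d", 1:10),
           sprintf("h%02d", 1:10))
  genos <- rep(c("XX", "XYm", "XYh"), each = 10)
  curves <- t(vapply(seq_along(ids), function(i) {
    normalize_melt(simulate_melt(alleles[[genos[i]]], tm, noise_sd = 0.005,
                                 seed = i))$fluorescence
  }, numeric(126)))
  rownames(curves) <- ids
  reference <- c(f01 = "XX", m01 = "XY", h01 = "XY")
  known_sex <- c(f01 = "F", m01 = "M", h01 = "H")
  res <- cluster_melt(curves, reference, known_sex = known_sex)
  got <- res$calls$cluster[match(ids, res$calls$sample_id)]
  expect_true(all(got[genos == "XX"] == "XX"))
  expect_true(all(got[genos != "XX"] == "XY"))   # pooled M + H
  expect_true(all(res$correlation[c("M", "H")] == 100))
})

test_that("clustering is invariant to sample order and grid subsampling", {
  panel <- hrm_panel(n_blind = 60, tm_spacing = 2.5, noise_sd = 0.01,
                     seed = 5)
  res1 <- cluster_melt(panel$curves, panel$reference)
  set.seed(2)
  res2 <- cluster_melt(panel$curves[sample(nrow(panel$curves)), ],
                       panel$reference)
  expect_identical(res1$calls, res2$calls)
  # subsample the temperature grid by 2 (allele spacing >= 5x the new step)
  sub <- panel$curves[, seq(1, ncol(panel$curves), by = 2)]
  res3 <- cluster_melt(sub, panel$reference)
  expect_identical(res1$calls$cluster, res3$calls$cluster)
  expect_error(cluster_melt(panel$curves, NULL), "reference")
})
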