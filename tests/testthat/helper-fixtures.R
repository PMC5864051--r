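# Shared fixtures and independent oracles. Expensive bundles are memoized
# per test run.

.fixtures <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generate_dataset(sim_config(seed = 11,
                                                   genes_per_reference = 4))
  .fixtures$small
}

# labelled transcript data frame (one row per present F/M/H bud transcript)
bundle_transcripts <- function(bundle, whorl = "bud28",
                               sexes = c("F", "M", "H")) {
  tx <- bundle$transcripts[bundle$transcripts$present &
                           bundle$transcripts$whorl == whorl &
                           bundle$transcripts$sex_type %in% sexes, ,
                           drop = FALSE]
  tx$transcript_id <- paste(tx$gene_id, tx$sex_type, tx$whorl, sep = "|")
  tx
}

# --- independent oracles ----------------------------------------------------

# O(n*m) substring-scan PCR oracle
naive_pcr <- function(template, forward, reverse, max_len = 5000L) {
  scan <- function(pat) {
    lp <- nchar(pat)
    n <- nchar(template)
    if (n < lp) return(integer(0))
    which(vapply(seq_len(n - lp + 1L), function(i)
      substring(template, i, i + lp - 1L) == pat, logical(1)))
  }
  f_pos <- scan(forward)
  rc <- revcomp_chr(reverse)
  r_pos <- scan(rc)
  out <- list()
  for (f in f_pos) for (r in r_pos) {
    if (r < f) next
    end <- r + nchar(reverse) - 1L
    len <- end - f + 1L
    if (len < max(nchar(forward), nchar(reverse)) || len > max_len) next
    out[[length(out) + 1L]] <- data.frame(start = f - 1L, end = end,
                                          length = len)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$length, res$start), , drop = FALSE]
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# positional-scan digestion oracle
naive_digest_fragments <- function(amplicon, site, cut) {
  n <- nchar(amplicon)
  ls <- nchar(site)
  cuts <- integer(0)
  i <- 1L
  while (i <= n - ls + 1L) {
    if (substring(amplicon, i, i + ls - 1L) == site) {
      cuts <- c(cuts, (i - 1L) + cut)
      i <- i + ls   # non-overlapping occurrences
    } else i <- i + 1L
  }
  diff(c(0L, cuts, n))
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Rebuild a haplotype transcript of a bundle gene from the gene model plus
# the truth ledger alone (the ledger-completeness oracle).
reconstruct_transcript <- function(bundle, gid, hap) {
  model <- bundle$models[[gid]]
  ref <- bundle$references[[model$reference_id]]
  spliced <- spliced_sequence(model, ref)
  led <- bundle$ledger[bundle$ledger$gene_id == gid &
                       bundle$ledger$haplotype == hap, , drop = FALSE]
  skip <- NA_integer_; retain <- NA_integer_
  for (i in seq_len(nrow(led))) {
    ev <- led[i, ]
    if (ev$event_type %in% c("MARKER_SNP", "SUBSTITUTION", "PREMATURE_STOP")) {
      alt <- sub(";.*", "", sub(".*>", "", ev$detail))
      substr(spliced, ev$position + 1L, ev$position + nchar(alt)) <- alt
    } else if (ev$event_type == "INTRON_RETENTION") {
      retain <- ev$position
    } else if (ev$event_type == "EXON_SKIP") {
      skip <- ev$position
    }
  }
  lens <- exon_lengths(model)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  exon_seqs <- substring(spliced, starts + 1L, ends)
  introns <- intron_sequences(model, ref)
  parts <- character(0)
  for (j in seq_along(exon_seqs)) {
    if (!is.na(skip) && j == skip) next
    parts <- c(parts, exon_seqs[j])
    if (!is.na(retain) && j == retain && j < length(exon_seqs))
      parts <- c(parts, introns[j])
  }
  paste(parts, collapse = "")
}

# Simulated HRM panel: normalized curves for blind + reference samples of
# the three diploid genotype classes at a marker with per-class allele Tm
# spacing `tm_spacing`.
hrm_panel <- function(n_blind = 200L, tm_spacing = 1.0, noise_sd = 0.01,
                      seed = 1L, grid = seq(65, 90, by = 0.2)) {
  tm <- c(X = 77, Ym = 77 + tm_spacing, Yh = 77 + 2 * tm_spacing)
  alleles <- list(XX = c("X", "X"), XYm = c("X", "Ym"), XYh = c("X", "Yh"))
  set.seed(seed)
  genos <- sample(names(alleles), n_blind, replace = TRUE)
  ids <- sprintf("b%04d", seq_len(n_blind))
  ref_ids <- sprintf("r%02d", 1:12)
  ref_genos <- rep(names(alleles), each = 4L)
  mk <- function(id_v, gn_v, seed0) {
    m <- t(vapply(seq_along(id_v), function(i) {
      raw <- simulate_melt(alleles[[gn_v[i]]], tm, d_tm = 1.0,
                           noise_sd = noise_sd, grid = grid,
                           seed = seed0 + i)
      normalize_melt(raw)$fluorescence
    }, numeric(length(grid))))
    rownames(m) <- id_v
    m
  }
  list(curves = rbind(mk(ids, genos, seed * 1000L),
                      mk(ref_ids, ref_genos, seed * 1000L + 600L)),
       blind_ids = ids, blind_genos = genos,
       reference = stats::setNames(ref_genos, ref_ids),
       known_sex = stats::setNames(c(XX = "F", XYm = "M",
                                     XYh = "H")[ref_genos], ref_ids))
}

# Junctions whose primer footprint overlaps a planted SNP on a haplotype
# (exact-match PCR loses the product when a SNP falls under a primer).
snp_touched_junctions <- function(bundle, gid, hap, a = 10L, b = 10L,
                                  rev_gap = 20L, rev_len = 20L) {
  model <- bundle$models[[gid]]
  junctions <- trisex:::spliced_junctions(model)
  gl <- bundle$ledger[bundle$ledger$gene_id == gid &
                      bundle$ledger$haplotype == hap &
                      bundle$ledger$event_type %in%
                        c("MARKER_SNP", "SUBSTITUTION", "PREMATURE_STOP"), ,
                      drop = FALSE]
  if (!nrow(gl)) return(integer(0))
  lens <- ifelse(gl$event_type == "MARKER_SNP", 1L, 3L)
  touched <- integer(0)
  for (i in seq_along(junctions)) {
    jp <- junctions[i]
    ivs <- rbind(c(jp - a, jp + b),
                 c(jp + b + rev_gap, jp + b + rev_gap + rev_len))
    for (r in seq_len(nrow(gl))) {
      s <- gl$position[r]; e <- s + lens[r]
      if (any(s < ivs[, 2] & e > ivs[, 1])) touched <- c(touched, i)
    }
  }
  unique(touched)
}
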