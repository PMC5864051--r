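# Synthetic-data generator: references, gene models, sex-typed transcript
# sets with planted SNP/splicing events, marker definitions, and progeny
# tables, together with a truth ledger recording every planted difference.

CHROM_CLASSES <- c("X", "Ym", "Yh")
SEX_TYPES <- c("F", "M", "H", "HM", "HF")

# haplotype expressed by each sex type (one representative transcript per
# sex type per gene; the abnormal hermaphrodites HM/HF carry the Yh
# haplotype of the normal hermaphrodite)
SEX_HAPLOTYPE <- c(F = "X", M = "Ym", H = "Yh", HM = "Yh", HF = "Yh")

# sex types whose transcripts carry a given haplotype's events
HAPLOTYPE_SEXES <- list(X = "F", Ym = "M", Yh = c("H", "HM", "HF"))

# tissues sampled per sex type (bud28: whole buds 28 days before flowering;
# third/fourth: stamen and carpel whorls at flowering)
SEX_WHORLS <- list(F = c("bud28", "fourth"),
                   M = c("bud28", "third"),
                   H = c("bud28", "third", "fourth"),
                   HM = c("bud28", "third"),
                   HF = c("bud28", "third", "fourth"))

UTR_LEN <- 30L

# Marker allele bases per chromosome class, placed at the third position of a
# glycine codon (GGN) so that marker SNPs are synonymous and do not perturb
# the amino-acid-based sex grouping.
MARKER_ALLELES <- list(
  THREE_SEX   = c(X = "T", Ym = "A", Yh = "C"),
  FEMALE_TYPE = c(X = "A", Ym = "G", Yh = "G"),
  MALE_TYPE   = c(X = "T", Ym = "C", Yh = "T")
)

# ---------------------------------------------------------------------------
# gene construction

# Draw the exon/intron structure and base (X-haplotype) sequence of one gene.
# The coding sequence starts with ATG, contains no internal stop, ends with
# TAA, and is flanked by 30-bp untranslated ends inside the terminal exons.
draw_gene <- function(cfg) {
  n_exons <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
  exon_lens <- sample(seq(cfg$exon_len[1], cfg$exon_len[2]), n_exons,
                      replace = TRUE)
  # pad the last exon so the CDS length is a codon multiple
  cds_len <- sum(exon_lens) - 2L * UTR_LEN
  pad <- (3L - cds_len %% 3L) %% 3L
  exon_lens[n_exons] <- exon_lens[n_exons] + pad
  cds_len <- cds_len + pad
  n_codons <- cds_len %/% 3L
  sense <- setdiff(all_codons(), STOP_CODONS)
  cds <- paste0("ATG",
                paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  spliced <- paste0(random_dna(UTR_LEN), cds, random_dna(UTR_LEN))
  ends <- cumsum(exon_lens)
  starts <- c(0L, ends[-n_exons])
  exon_seqs <- substring(spliced, starts + 1L, ends)
  intron_lens <- if (n_exons > 1L)
    sample(seq(cfg$intron_len[1], cfg$intron_len[2]), n_exons - 1L,
           replace = TRUE) else integer(0)
  intron_seqs <- vapply(intron_lens, function(l)
    paste0("GT", random_dna(l - 4L), "AG"), character(1))
  list(exon_seqs = exon_seqs, intron_seqs = intron_seqs,
       exon_lens = exon_lens, intron_lens = intron_lens,
       cds_start = UTR_LEN, cds_len = cds_len, n_exons = n_exons)
}

# Spliced coordinates of codon k (1-based) of a gene.
codon_interval <- function(gene, k) {
  s <- gene$cds_start + 3L * (k - 1L)
  c(s, s + 3L)  # 0-based half-open on the spliced transcript
}

# Which exon fully contains spliced interval [s, e)? 0 when none.
exon_containing <- function(gene, s, e) {
  ends <- cumsum(gene$exon_lens)
  starts <- c(0L, ends[-gene$n_exons])
  hit <- which(starts <= s & e <= ends)
  if (length(hit)) hit[1L] else 0L
}

set_spliced_base <- function(exon_seqs, exon_lens, pos, base) {
  ends <- cumsum(exon_lens)
  starts <- c(0L, ends[-length(ends)])
  i <- which(starts <= pos & pos < ends)[1L]
  off <- pos - starts[i] + 1L
  substr(exon_seqs[i], off, off) <- base
  exon_seqs
}

get_spliced_base <- function(exon_seqs, exon_lens, pos) {
  ends <- cumsum(exon_lens)
  starts <- c(0L, ends[-length(ends)])
  i <- which(starts <= pos & pos < ends)[1L]
  substring(exon_seqs[i], pos - starts[i] + 1L, pos - starts[i] + 1L)
}

# Assemble a haplotype transcript from (possibly substituted) exon
# sequences, applying an exon skip and/or intron retention.
assemble_transcript <- function(exon_seqs, intron_seqs, skip_exon = NA,
                                retain_intron = NA) {
  parts <- character(0)
  n <- length(exon_seqs)
  for (j in seq_len(n)) {
    if (!is.na(skip_exon) && j == skip_exon) next
    parts <- c(parts, exon_seqs[j])
    if (!is.na(retain_intron) && j == retain_intron && j < n)
      parts <- c(parts, intron_seqs[j])
  }
  paste(parts, collapse = "")
}

# ---------------------------------------------------------------------------
# event planting

# Plant per-haplotype events on one gene; returns the three haplotype
# transcripts plus ledger rows. `marker` (optional) fixes a synonymous
# marker SNP with class-specific alleles.
plant_gene_events <- function(gene, cfg, marker_class = NULL) {
  n_codons <- gene$cds_len %/% 3L
  ledger <- list()
  marker <- NULL
  reserved_codons <- integer(0)

  if (!is.null(marker_class)) {
    # pick a codon in the central exon, fully inside the CDS
    target_exon <- max(1L, ceiling(gene$n_exons / 2))
    cand <- Filter(function(k) {
      iv <- codon_interval(gene, k)
      exon_containing(gene, iv[1], iv[2]) == target_exon
    }, 2:(n_codons - 1L))
    if (!length(cand)) {
      cand <- Filter(function(k) {
        iv <- codon_interval(gene, k)
        exon_containing(gene, iv[1], iv[2]) > 0L
      }, 2:(n_codons - 1L))
    }
    k <- cand[[ceiling(length(cand) / 2)]]
    iv <- codon_interval(gene, k)
    alleles <- MARKER_ALLELES[[marker_class]]
    # rewrite the base codon to GG + X allele (glycine, 4-fold degenerate)
    gene$exon_seqs <- set_spliced_base(gene$exon_seqs, gene$exon_lens, iv[1], "G")
    gene$exon_seqs <- set_spliced_base(gene$exon_seqs, gene$exon_lens, iv[1] + 1L, "G")
    gene$exon_seqs <- set_spliced_base(gene$exon_seqs, gene$exon_lens, iv[1] + 2L,
                                       alleles[["X"]])
    marker <- list(class = marker_class, codon = k,
                   spliced_pos = iv[1] + 2L, alleles = alleles)
    reserved_codons <- k
  }

  haps <- list()
  for (hap in CHROM_CLASSES) {
    exon_seqs <- gene$exon_seqs
    sexes <- paste(HAPLOTYPE_SEXES[[hap]], collapse = ",")

    if (!is.null(marker) && marker$alleles[[hap]] != marker$alleles[["X"]]) {
      exon_seqs <- set_spliced_base(exon_seqs, gene$exon_lens,
                                    marker$spliced_pos, marker$alleles[[hap]])
      ledger[[length(ledger) + 1L]] <- data.frame(
        haplotype = hap, event_type = "MARKER_SNP",
        position = marker$spliced_pos,
        detail = paste0(marker$alleles[["X"]], ">", marker$alleles[[hap]]),
        sex_types = sexes)
    }

    used <- reserved_codons
    # non-synonymous substitution
    if (stats::runif(1) < cfg$substitution_rate) {
      k <- sample(setdiff(2:(n_codons - 1L), used), 1L)
      used <- c(used, k)
      iv <- codon_interval(gene, k)
      old <- paste0(get_spliced_base(exon_seqs, gene$exon_lens, iv[1]),
                    get_spliced_base(exon_seqs, gene$exon_lens, iv[1] + 1L),
                    get_spliced_base(exon_seqs, gene$exon_lens, iv[1] + 2L))
      aa_old <- Biostrings::GENETIC_CODE[[old]]
      new <- sample(names(which(Biostrings::GENETIC_CODE != aa_old &
                                Biostrings::GENETIC_CODE != "*")), 1L)
      for (b in 0:2)
        exon_seqs <- set_spliced_base(exon_seqs, gene$exon_lens, iv[1] + b,
                                      substring(new, b + 1L, b + 1L))
      ledger[[length(ledger) + 1L]] <- data.frame(
        haplotype = hap, event_type = "SUBSTITUTION", position = iv[1],
        detail = paste0(old, ">", new), sex_types = sexes)
    }
    # premature stop in the middle third of the CDS
    if (stats::runif(1) < cfg$as_event_rates[["PREMATURE_STOP"]]) {
      lo <- max(2L, floor(n_codons / 3))
      hi <- min(n_codons - 1L, ceiling(2 * n_codons / 3))
      k <- sample(setdiff(lo:hi, used), 1L)
      iv <- codon_interval(gene, k)
      old <- paste0(get_spliced_base(exon_seqs, gene$exon_lens, iv[1]),
                    get_spliced_base(exon_seqs, gene$exon_lens, iv[1] + 1L),
                    get_spliced_base(exon_seqs, gene$exon_lens, iv[1] + 2L))
      for (b in 0:2)
        exon_seqs <- set_spliced_base(exon_seqs, gene$exon_lens, iv[1] + b,
                                      substring("TAA", b + 1L, b + 1L))
      ledger[[length(ledger) + 1L]] <- data.frame(
        haplotype = hap, event_type = "PREMATURE_STOP", position = iv[1],
        detail = paste0(old, ">TAA;codon=", k), sex_types = sexes)
    }
    retain <- NA_integer_
    if (gene$n_exons > 1L &&
        stats::runif(1) < cfg$as_event_rates[["INTRON_RETENTION"]]) {
      retain <- sample.int(gene$n_exons - 1L, 1L)
      ledger[[length(ledger) + 1L]] <- data.frame(
        haplotype = hap, event_type = "INTRON_RETENTION", position = retain,
        detail = paste0("intron_len=", gene$intron_lens[retain]),
        sex_types = sexes)
    }
    skip <- NA_integer_
    if (gene$n_exons > 2L &&
        stats::runif(1) < cfg$as_event_rates[["EXON_SKIP"]]) {
      # keep splice events coherent: never skip an exon flanking a retained
      # intron on the same haplotype
      cand <- setdiff(2:(gene$n_exons - 1L),
                      if (!is.na(retain)) c(retain, retain + 1L) else integer(0))
      if (length(cand)) {
        skip <- if (length(cand) == 1L) cand else sample(cand, 1L)
        ledger[[length(ledger) + 1L]] <- data.frame(
          haplotype = hap, event_type = "EXON_SKIP", position = skip,
          detail = paste0("exon_len=", gene$exon_lens[skip]),
          sex_types = sexes)
      }
    }
    haps[[hap]] <- list(
      transcript = assemble_transcript(exon_seqs, gene$intron_seqs,
                                       skip_exon = skip,
                                       retain_intron = retain),
      skip = skip, retain = retain)
  }
  list(gene = gene, haplotypes = haps,
       ledger = if (length(ledger)) do.call(rbind, ledger) else NULL,
       marker = marker)
}

# Truth category by the fixed precedence over the planted events of the
# present F/M/H haplotypes; NA when fewer than two sex types are present.
truth_category <- function(hap_info, present_haps, truncated) {
  if (length(present_haps) < 2L) return(NA_character_)
  skips <- any(!is.na(vapply(hap_info[present_haps], `[[`, 0L, "skip")))
  rets <- any(!is.na(vapply(hap_info[present_haps], `[[`, 0L, "retain")))
  if (skips) return("EXON_JUMP")
  if (rets) return("INTRON_JUMP")
  if (any(truncated[present_haps])) return("AA_SHORT")
  "NO_CHANGE"
}

truth_sex_group <- function(present, aa) {
  # present: named logical over F/M/H; aa: named protein strings
  sexes <- names(present)[present]
  if (length(sexes) < 2L) return("NONE")
  pairs <- utils::combn(sexes, 2L)
  same <- apply(pairs, 2L, function(p) identical(aa[[p[1]]], aa[[p[2]]]))
  if (length(sexes) == 2L) return(if (!same) "TYPE_1" else "NONE")
  n_same <- sum(same)
  if (n_same == 0L) return("TYPE_2")
  if (n_same == 1L) return("TYPE_3")
  "NONE"
}

# ---------------------------------------------------------------------------
# dataset generator

#' Generate a synthetic sex-typed transcriptome dataset
#'
#' Simulates the full input bundle the screening pipeline consumes: reference
#' regions (one per sex-chromosome class), multi-exon gene models, one
#' representative transcript per gene per sex type carrying planted
#' sex-specific SNPs and splicing events (intron retention, exon skipping,
#' premature stops), per-tissue expression values, diagnostic SNP markers of
#' the three segregation classes, and a blind progeny panel from a
#' hermaphrodite-by-male cross. Every planted difference is recorded in the
#' truth ledger, against which the classifier modules can be scored.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_bundle` list with elements `config`, `references` (named
#'   character vector), `models` (named list of gene models), `transcripts`
#'   (data frame: gene_id, sex_type, whorl, present, expression, sequence),
#'   `ledger` (data frame of planted events), `truth` (per-gene presence,
#'   category and sex-grouping type plus haplotype proteins), `markers`
#'   (marker definitions) and `progeny` (see [generate_progeny()]).
#' @examples
#' bundle <- generate_dataset(sim_config(seed = 7, genes_per_reference = 2))
#' head(bundle$truth)
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config

  n_genes <- cfg$n_references * cfg$genes_per_reference
  marker_gene_idx <- integer(0)
  if (length(cfg$snp_sex_classes)) {
    marker_gene_idx <- if (cfg$n_references >= length(cfg$snp_sex_classes))
      (seq_along(cfg$snp_sex_classes) - 1L) * cfg$genes_per_reference + 1L
    else seq_along(cfg$snp_sex_classes)
  }

  # -- structure ------------------------------------------------------------
  genes <- with_seed(sub_seed(cfg$seed, 1L), {
    lapply(seq_len(n_genes), function(i) draw_gene(cfg))
  })

  # -- events and presence --------------------------------------------------
  planted <- with_seed(sub_seed(cfg$seed, 2L), {
    lapply(seq_len(n_genes), function(i) {
      mclass <- if (i %in% marker_gene_idx)
        cfg$snp_sex_classes[match(i, marker_gene_idx)] else NULL
      p <- plant_gene_events(genes[[i]], cfg, marker_class = mclass)
      pat <- if (!is.null(mclass)) "three_sex" else
        sample(names(cfg$presence_probs), 1L, prob = cfg$presence_probs)
      p$presence <- switch(pat,
                           three_sex = c("F", "M", "H"),
                           two_sex = c("M", "H"),
                           one_sex = sample(c("F", "M", "H"), 1L))
      p
    })
  })

  # -- assemble references and models ---------------------------------------
  spacers <- with_seed(sub_seed(cfg$seed, 5L), {
    replicate(n_genes + cfg$n_references,
              random_dna(sample(200:400, 1L)))
  })
  references <- character(cfg$n_references)
  ref_class <- rep_len(CHROM_CLASSES, cfg$n_references)
  names(references) <- sprintf("ref%02d_%s", seq_len(cfg$n_references),
                               ref_class)
  models <- list()
  gene_meta <- list()
  idx <- 0L
  sp <- 0L
  for (r in seq_len(cfg$n_references)) {
    sp <- sp + 1L
    seq_parts <- spacers[sp]
    pos <- nchar(spacers[sp])
    for (g in seq_len(cfg$genes_per_reference)) {
      idx <- idx + 1L
      gn <- planted[[idx]]$gene
      gid <- sprintf("g%03d", idx)
      # interleave exons and introns to get the genomic gene sequence
      parts <- character(0)
      for (j in seq_len(gn$n_exons)) {
        parts <- c(parts, gn$exon_seqs[j])
        if (j < gn$n_exons) parts <- c(parts, gn$intron_seqs[j])
      }
      genomic <- paste(parts, collapse = "")
      ends <- cumsum(gn$exon_lens + c(gn$intron_lens, 0L))
      exon_starts <- pos + c(0L, ends[-gn$n_exons])
      exons <- data.frame(start = exon_starts,
                          end = exon_starts + gn$exon_lens)
      models[[gid]] <- gene_model(gid, names(references)[r], exons,
                                  cds_start = gn$cds_start,
                                  cds_end = gn$cds_start + gn$cds_len)
      gene_meta[[gid]] <- planted[[idx]]
      sp <- sp + 1L
      seq_parts <- c(seq_parts, genomic, spacers[sp])
      pos <- pos + nchar(genomic) + nchar(spacers[sp])
    }
    references[r] <- paste(seq_parts, collapse = "")
  }
  gene_ids <- names(models)

  # -- ledger ----------------------------------------------------------------
  ledger <- do.call(rbind, lapply(gene_ids, function(gid) {
    l <- gene_meta[[gid]]$ledger
    if (is.null(l)) return(NULL)
    cbind(data.frame(gene_id = gid), l)
  }))
  if (is.null(ledger))
    ledger <- data.frame(gene_id = character(0), haplotype = character(0),
                         event_type = character(0), position = integer(0),
                         detail = character(0), sex_types = character(0))

  # -- markers ---------------------------------------------------------------
  markers <- do.call(rbind, lapply(seq_along(marker_gene_idx), function(j) {
    gid <- gene_ids[marker_gene_idx[j]]
    mk <- gene_meta[[gid]]$marker
    model <- models[[gid]]
    starts_sp <- spliced_exon_starts(model)
    lens <- exon_lengths(model)
    i <- which(starts_sp <= mk$spliced_pos &
               mk$spliced_pos < starts_sp + lens)[1L]
    gpos <- model$exons$start[i] + (mk$spliced_pos - starts_sp[i])
    tm_levels <- sort(unique(mk$alleles))
    tms <- 77 + (match(mk$alleles, tm_levels) - 1) * cfg$tm_spacing
    names(tms) <- names(mk$alleles)
    data.frame(marker = paste0(gid, "_", mk$class), gene_id = gid,
               class = mk$class, spliced_pos = mk$spliced_pos,
               genomic_pos = gpos,
               allele_X = mk$alleles[["X"]], allele_Ym = mk$alleles[["Ym"]],
               allele_Yh = mk$alleles[["Yh"]],
               tm_X = tms[["X"]], tm_Ym = tms[["Ym"]], tm_Yh = tms[["Yh"]])
  }))

  # -- transcripts and expression -------------------------------------------
  transcripts <- with_seed(sub_seed(cfg$seed, 3L), {
    base <- stats::rlnorm(length(gene_ids),
                          cfg$expression_lognormal_params[["meanlog"]],
                          cfg$expression_lognormal_params[["sdlog"]])
    names(base) <- gene_ids
    rows <- list()
    for (gid in gene_ids) {
      gm <- gene_meta[[gid]]
      for (sex in SEX_TYPES) {
        base_sex <- if (sex %in% c("HM", "HF")) "H" else sex
        present <- base_sex %in% gm$presence
        for (whorl in SEX_WHORLS[[sex]]) {
          expr <- if (present)
            base[gid] * exp(stats::rnorm(1L, 0, cfg$expression_noise_sd)) else 0
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gid, sex_type = sex, whorl = whorl, present = present,
            expression = expr,
            sequence = if (present)
              gm$haplotypes[[SEX_HAPLOTYPE[[sex]]]]$transcript
            else NA_character_)
        }
      }
    }
    do.call(rbind, rows)
  })
  rownames(transcripts) <- NULL

  # -- truth -----------------------------------------------------------------
  truth <- do.call(rbind, lapply(gene_ids, function(gid) {
    gm <- gene_meta[[gid]]
    present <- c(F = "F" %in% gm$presence, M = "M" %in% gm$presence,
                 H = "H" %in% gm$presence)
    n_codons <- (models[[gid]]$cds_end - models[[gid]]$cds_start) %/% 3L
    aa <- list(); truncated <- c(X = FALSE, Ym = FALSE, Yh = FALSE)
    for (hap in CHROM_CLASSES) {
      tx <- gm$haplotypes[[hap]]$transcript
      tr <- translate_to_stop(substring(tx, UTR_LEN + 1L, nchar(tx)))
      aa[[hap]] <- tr$aa
      truncated[hap] <- !is.na(tr$stop_codon) && tr$stop_codon < n_codons
    }
    aa_sex <- list(F = aa[["X"]], M = aa[["Ym"]], H = aa[["Yh"]])
    data.frame(gene_id = gid, reference_id = models[[gid]]$reference_id,
               present_F = present[["F"]], present_M = present[["M"]],
               present_H = present[["H"]], n_sexes = sum(present),
               category = truth_category(
                 gm$haplotypes,
                 CHROM_CLASSES[c(present[["F"]], present[["M"]], present[["H"]])],
                 truncated),
               sex_group_type = truth_sex_group(present, aa_sex),
               aa_F = aa_sex$F, aa_M = aa_sex$M, aa_H = aa_sex$H)
  }))

  # -- progeny ---------------------------------------------------------------
  progeny <- generate_progeny(c("XYh", "XYm"), cfg$progeny_n,
                              seed = sub_seed(cfg$seed, 4L),
                              markers = markers)

  structure(list(config = cfg, references = references, models = models,
                 transcripts = transcripts, ledger = ledger, truth = truth,
                 markers = markers, progeny = progeny),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic screening dataset\n")
  cat(sprintf("  references : %d\n", length(x$references)))
  cat(sprintf("  genes      : %d\n", length(x$models)))
  cat(sprintf("  transcripts: %d (%d present)\n", nrow(x$transcripts),
              sum(x$transcripts$present)))
  cat(sprintf("  ledger     : %d planted events\n", nrow(x$ledger)))
  cat(sprintf("  markers    : %s\n", paste(x$markers$class, collapse = ", ")))
  cat(sprintf("  progeny    : %d samples\n", nrow(x$progeny)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# progeny

GENOTYPE_CHROMS <- list(XX = c("X", "X"), XYm = c("X", "Ym"),
                        XYh = c("X", "Yh"))
GENOTYPE_PHENOTYPE <- c(XX = "F", XYm = "M", XYh = "H")

#' Simulate progeny of a cross under Y/Y zygote lethality
#'
#' Offspring genotypes are drawn uniformly from the four gametic
#' combinations of the two parents; combinations pairing two Y-class
#' chromosomes (Ym/Ym, Ym/Yh, Yh/Yh) are lethal and are rejected and
#' redrawn, so a hermaphrodite-by-male cross (XYh x XYm) segregates
#' 1:1:1 (female : hermaphrodite : male).
#'
#' @param cross Character vector of the two parent genotypes, each one of
#'   `"XX"`, `"XYm"`, `"XYh"`.
#' @param n Number of offspring.
#' @param seed Integer seed.
#' @param markers Optional marker table (as in a [generate_dataset()]
#'   bundle); when supplied, per-marker allele pairs are appended.
#' @return A data frame with `sample_id`, `genotype`, `phenotype`, and, when
#'   markers are given, `<marker>_alleles` columns.
#' @examples
#' tab <- generate_progeny(c("XYh", "XYm"), 96, seed = 1)
#' table(tab$phenotype)
#' @export
generate_progeny <- function(cross, n, seed = 1L, markers = NULL) {
  stopifnot(length(cross) == 2L, n >= 1L)
  if (!all(cross %in% names(GENOTYPE_CHROMS)))
    stop("parents must be one of XX, XYm, XYh")
  if (all(cross == "XX"))
    stop("no cross possible: both parents are XX")
  g1 <- GENOTYPE_CHROMS[[cross[1]]]
  g2 <- GENOTYPE_CHROMS[[cross[2]]]
  with_seed(seed, {
    a <- sample(g1, n, replace = TRUE)
    b <- sample(g2, n, replace = TRUE)
    lethal <- a != "X" & b != "X"
    while (any(lethal)) {  # rejection sampling of Y/Y zygotes
      k <- sum(lethal)
      a[lethal] <- sample(g1, k, replace = TRUE)
      b[lethal] <- sample(g2, k, replace = TRUE)
      lethal <- a != "X" & b != "X"
    }
    y <- ifelse(a == "X", b, a)
    genotype <- ifelse(y == "X", "XX", paste0("X", y))
    out <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                      genotype = genotype,
                      phenotype = GENOTYPE_PHENOTYPE[genotype])
    if (!is.null(markers) && nrow(markers)) {
      for (i in seq_len(nrow(markers))) {
        al <- c(X = markers$allele_X[i], Ym = markers$allele_Ym[i],
                Yh = markers$allele_Yh[i])
        out[[paste0(markers$marker[i], "_alleles")]] <-
          paste0(al[a], "/", al[b])
      }
    }
    rownames(out) <- NULL
    out
  })
}
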