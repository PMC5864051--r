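# Cohort generator for the functional-map integration: per-sample, per-locus
# relative expression, junction RT-PCR products and SNP genotype classes for
# the five flower classes, with the planted truth.

# Expression multipliers per locus and flower class (relative to the
# unchanged baseline 1): elevated expression is planted at x8 and reduced
# expression at x1/8 so HIGH/LOW calls are unambiguous at the 2x / 0.5x
# thresholds. F profiles are taken in the fourth whorl, the others in the
# third.
COHORT_EXPR <- list(
  CpSERK   = c(M = 1, H = 1, HM = 1, HF = 1, F = 1),
  CpSVPL   = c(M = 8, H = 1 / 8, HM = 8, HF = 1 / 8, F = 1 / 8),
  CpCAF1AL = c(M = 8, H = 8, HM = 1 / 8, HF = 1 / 8, F = 1 / 8)
)

# Classes with an alternative-splicing form (a retained diagnostic intron)
# at each locus.
COHORT_AS <- list(
  CpSERK   = c("HM", "HF", "F"),
  CpSVPL   = character(0),
  CpCAF1AL = c("HM", "HF", "F")
)

COHORT_GENOTYPE <- c(M = "XYm", H = "XYh", HM = "XYh", HF = "XYh", F = "XX")
COHORT_WHORL <- c(M = "third", H = "third", HM = "third", HF = "third",
                  F = "fourth")
COHORT_TRUE_CALL <- c(M = "M", H = "H", HM = "HM", HF = "HF",
                      F = "F_fourth_whorl")

#' Generate a flower cohort for functional-map calling
#'
#' Simulates `n` flowers across the five classes (female F, male M, normal
#' hermaphrodite H, female-sterile HM, carpellate HF). Three canonical
#' sex-related loci are built as real multi-exon gene models; for classes
#' with a planted splicing form the diagnostic intron is retained in the
#' locus transcript, and junction RT-PCR products are computed by running
#' the in-silico assays against the class transcript. Expression values are
#' housekeeping-normalized multiples of the baseline with optional
#' log-normal noise.
#'
#' @param n Number of flowers.
#' @param class_probs Named sampling probabilities over the five classes.
#' @param expr_noise_sd Standard deviation of the expression noise on the
#'   natural-log scale (0 = noise free).
#' @param seed Integer seed.
#' @return A `flower_cohort` list: `samples` (long data frame: sample_id,
#'   true_class, whorl, locus, expression, genotype), `junctions` (long data
#'   frame of per-sample junction products), `truth` (sample_id, true_class,
#'   expected call), `models`, `references`.
#' @export
generate_flower_cohort <- function(n = 200L,
                                   class_probs = c(F = 0.3, M = 0.25,
                                                   H = 0.25, HM = 0.1,
                                                   HF = 0.1),
                                   expr_noise_sd = 0.25, seed = 1L) {
  stopifnot(n >= 1L, all(names(COHORT_GENOTYPE) %in% names(class_probs)))

  # canonical locus models (fixed structure, independent of n)
  loci <- with_seed(sub_seed(seed, 11L), {
    cfg <- sim_config(seed = 1L, exons_per_gene = c(4L, 5L))
    lapply(FLOWER_LOCI, function(l) draw_gene(cfg))
  })
  names(loci) <- FLOWER_LOCI

  models <- list(); references <- character(0); primers <- list()
  tx_normal <- list(); tx_as <- list()
  for (l in FLOWER_LOCI) {
    g <- loci[[l]]
    parts <- character(0)
    for (j in seq_len(g$n_exons)) {
      parts <- c(parts, g$exon_seqs[j])
      if (j < g$n_exons) parts <- c(parts, g$intron_seqs[j])
    }
    ref <- paste(parts, collapse = "")
    references[[paste0("ref_", l)]] <- ref
    ends <- cumsum(g$exon_lens + c(g$intron_lens, 0L))
    starts <- c(0L, ends[-g$n_exons])
    models[[l]] <- gene_model(l, paste0("ref_", l),
                              data.frame(start = starts,
                                         end = starts + g$exon_lens),
                              cds_start = g$cds_start,
                              cds_end = g$cds_start + g$cds_len)
    primers[[l]] <- design_junction_primers(models[[l]], ref)
    tx_normal[[l]] <- assemble_transcript(g$exon_seqs, g$intron_seqs)
    # diagnostic retained intron: the middle one
    di <- max(1L, (g$n_exons - 1L) %/% 2L)
    tx_as[[l]] <- assemble_transcript(g$exon_seqs, g$intron_seqs,
                                      retain_intron = di)
  }

  # junction products per locus and splicing state (shared by samples)
  products <- list()
  for (l in FLOWER_LOCI) {
    products[[l]] <- list(
      NO_AS = junction_rtpcr(tx_normal[[l]], primers[[l]]),
      AS = junction_rtpcr(tx_as[[l]], primers[[l]]))
  }

  with_seed(sub_seed(seed, 12L), {
    classes <- sample(names(class_probs), n, replace = TRUE,
                      prob = class_probs)
    ids <- sprintf("fl%04d", seq_len(n))
    samples <- list(); junctions <- list()
    for (i in seq_len(n)) {
      cl <- classes[i]
      for (l in FLOWER_LOCI) {
        mult <- COHORT_EXPR[[l]][[cl]]
        value <- mult * exp(stats::rnorm(1L, 0, expr_noise_sd))
        state <- if (cl %in% COHORT_AS[[l]]) "AS" else "NO_AS"
        samples[[length(samples) + 1L]] <- data.frame(
          sample_id = ids[i], true_class = cl, whorl = COHORT_WHORL[[cl]],
          locus = l, expression = value,
          genotype = COHORT_GENOTYPE[[cl]], as_state = state)
        jp <- products[[l]][[state]]
        junctions[[length(junctions) + 1L]] <- cbind(
          data.frame(sample_id = ids[i], locus = l), jp)
      }
    }
    truth <- data.frame(sample_id = ids, true_class = classes,
                        expected_call = COHORT_TRUE_CALL[classes])
    rownames(truth) <- NULL
    structure(list(samples = do.call(rbind, samples),
                   junctions = do.call(rbind, junctions),
                   truth = truth, models = models, references = references),
              class = "flower_cohort")
  })
}

#' Call flower types for a cohort
#'
#' Runs the integration pipeline over a generated cohort: expression classes
#' are assigned against the pooled panel of all housekeeping-normalized
#' locus values (whose median sits at the unchanged baseline), splicing
#' flags are derived from the junction RT-PCR products, and each sample's
#' locus profile is matched against the rule table for its whorl.
#'
#' @param cohort A [generate_flower_cohort()] object.
#' @param rules Rule table (default [flower_rule_table()]).
#' @return Data frame: sample_id, true_class, expected_call, call, correct,
#'   stable (stable-hermaphrodite flag, NA unless the call is H).
#' @export
call_flower_types <- function(cohort, rules = flower_rule_table()) {
  stopifnot(inherits(cohort, "flower_cohort"))
  panel <- cohort$samples$expression
  out <- list()
  for (id in unique(cohort$samples$sample_id)) {
    rows <- cohort$samples[cohort$samples$sample_id == id, , drop = FALSE]
    whorl <- rows$whorl[1L]
    profile <- list()
    for (l in FLOWER_LOCI) {
      r <- rows[rows$locus == l, , drop = FALSE]
      jp <- cohort$junctions[cohort$junctions$sample_id == id &
                             cohort$junctions$locus == l, , drop = FALSE]
      profile[[l]] <- list(
        expr = classify_expression(r$expression, panel),
        as = derive_as_flag(jp),
        genotype = r$genotype)
    }
    pred <- predict_flower_type(profile, whorl, rules)
    stable <- NA
    if (identical(pred$call, "H"))
      stable <- call_stable_hermaphrodite(profile, whorl, rules)
    out[[length(out) + 1L]] <- data.frame(
      sample_id = id, call = pred$call, stable = stable)
  }
  calls <- do.call(rbind, out)
  res <- merge(cohort$truth, calls, by = "sample_id", sort = TRUE)
  res$correct <- res$call == res$expected_call
  res[order(res$sample_id),
      c("sample_id", "true_class", "expected_call", "call", "correct",
        "stable")]
}
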