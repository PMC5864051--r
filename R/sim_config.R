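#' Simulation configuration
#'
#' Builds and validates the configuration used by [generate_dataset()]. The
#' defaults describe a desk-scale version of a trioecious screening study:
#' three reference regions (one per sex-chromosome class X, Ym and Yh), a
#' handful of multi-exon genes per region, sex-specific SNP markers of the
#' three diagnostic classes, and alternative-splicing events planted per gene
#' per sex haplotype.
#'
#' @param seed Integer root seed. Every stochastic component derives its own
#'   sub-stream from it, so bundles are reproducible byte for byte.
#' @param n_references Number of reference regions (default 3, one per
#'   chromosome class).
#' @param genes_per_reference Genes simulated on each reference.
#' @param exons_per_gene Integer range (length 2) for the number of exons.
#' @param exon_len,intron_len Base-pair ranges (length 2) for exon and intron
#'   lengths. Exons must be at least 60 bp so that the terminal exons can
#'   host the 30-bp untranslated ends flanking the coding sequence.
#' @param snp_sex_classes Marker classes to plant; subset of
#'   `"THREE_SEX"`, `"FEMALE_TYPE"`, `"MALE_TYPE"`.
#' @param as_event_rates Named probabilities (per gene, per sex haplotype) for
#'   `INTRON_RETENTION`, `EXON_SKIP` and `PREMATURE_STOP` events.
#' @param substitution_rate Probability, per gene per sex haplotype, of one
#'   planted non-synonymous substitution (drives the sex-grouping types).
#' @param presence_probs Named probabilities for a gene's expression pattern:
#'   `three_sex` (F, M and H), `two_sex` (M and H only, the candidate class)
#'   and `one_sex` (a single random sex type).
#' @param expression_lognormal_params Named `meanlog`/`sdlog` of the
#'   log-normal baseline expression draw (linear arbitrary units).
#' @param expression_noise_sd Standard deviation, on the log scale, of the
#'   per-sample multiplicative expression noise.
#' @param noise_sd_melt Gaussian noise (fluorescence units) added to
#'   simulated melt curves.
#' @param tm_spacing Melting-temperature spacing (deg C) between adjacent
#'   marker alleles.
#' @param progeny_n Number of progeny drawn for the blind segregation panel.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, genes_per_reference = 2)
#' @export
sim_config <- function(seed = 1L,
                       n_references = 3L,
                       genes_per_reference = 6L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(120L, 300L),
                       intron_len = c(80L, 150L),
                       snp_sex_classes = c("THREE_SEX", "FEMALE_TYPE", "MALE_TYPE"),
                       as_event_rates = c(INTRON_RETENTION = 0.2,
                                          EXON_SKIP = 0.2,
                                          PREMATURE_STOP = 0.2),
                       substitution_rate = 0.3,
                       presence_probs = c(three_sex = 0.7, two_sex = 0.25,
                                          one_sex = 0.05),
                       expression_lognormal_params = c(meanlog = 3, sdlog = 0.5),
                       expression_noise_sd = 0.1,
                       noise_sd_melt = 0.01,
                       tm_spacing = 1.0,
                       progeny_n = 96L) {
  cfg <- list(
    seed = as.integer(seed),
    n_references = as.integer(n_references),
    genes_per_reference = as.integer(genes_per_reference),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len),
    snp_sex_classes = snp_sex_classes,
    as_event_rates = as_event_rates,
    substitution_rate = substitution_rate,
    presence_probs = presence_probs,
    expression_lognormal_params = expression_lognormal_params,
    expression_noise_sd = expression_noise_sd,
    noise_sd_melt = noise_sd_melt,
    tm_spacing = tm_spacing,
    progeny_n = as.integer(progeny_n)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng_ok <- function(r) length(r) == 2L && !anyNA(r) && r[1] <= r[2] && r[1] >= 1L
  if (cfg$n_references < 1L || cfg$genes_per_reference < 1L || cfg$progeny_n < 1L)
    stop("configuration error: all counts must be >= 1")
  if (!rng_ok(cfg$exons_per_gene) || !rng_ok(cfg$exon_len) || !rng_ok(cfg$intron_len))
    stop("configuration error: ranges must be non-empty (min <= max, min >= 1)")
  if (cfg$exons_per_gene[1] < 2L)
    stop("configuration error: genes need at least 2 exons")
  if (cfg$exon_len[1] < 60L)
    stop("configuration error: exon length range too short to host the ",
         "untranslated ends and a coding sequence (need >= 60 bp)")
  if (cfg$intron_len[1] < 10L)
    stop("configuration error: introns must be at least 10 bp")
  probs <- c(cfg$as_event_rates, cfg$substitution_rate, cfg$presence_probs)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("configuration error: all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$presence_probs) - 1) > 1e-8)
    stop("configuration error: presence_probs must sum to 1")
  need <- c("INTRON_RETENTION", "EXON_SKIP", "PREMATURE_STOP")
  if (!all(need %in% names(cfg$as_event_rates)))
    stop("configuration error: as_event_rates must name ",
         paste(need, collapse = ", "))
  known <- c("THREE_SEX", "FEMALE_TYPE", "MALE_TYPE")
  if (!all(cfg$snp_sex_classes %in% known))
    stop("configuration error: unknown marker class in snp_sex_classes")
  if (length(cfg$snp_sex_classes) >
      cfg$n_references * cfg$genes_per_reference)
    stop("configuration error: more marker classes than genes available")
  if (!all(c("meanlog", "sdlog") %in% names(cfg$expression_lognormal_params)))
    stop("configuration error: expression_lognormal_params must name meanlog and sdlog")
  invisible(cfg)
}
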