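# In-silico marker assays: exact-match PCR, restriction digestion
# (PCR-RFLP), exon-junction RT-PCR, and high-resolution-melting curve
# simulation, normalization and clustering.

# Built-in restriction enzymes: recognition site and 0-based cut offset on
# the top strand (NdeI CA^TATG, SpeI A^CTAGT).
RESTRICTION_ENZYMES <- list(
  NdeI = list(site = "CATATG", cut = 2L),
  SpeI = list(site = "ACTAGT", cut = 1L)
)

find_exact <- function(template, pattern) {
  hits <- gregexpr(pattern, template, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' In-silico PCR with exact primer matching
#'
#' The forward primer is matched exactly on the plus strand; the reverse
#' complement of the reverse primer is matched downstream. An amplicon spans
#' the first base of a forward match through the last base of a
#' reverse-complement match. All pairings up to `max_len` are returned,
#' nearest pairing first; no match yields an empty result (modelling absence
#' of a PCR product).
#'
#' @param template Character scalar template sequence.
#' @param forward,reverse Primer sequences, 5'->3', at least 15 nt.
#' @param max_len Maximum amplicon length (default 5000 bp).
#' @return Data frame: start, end (0-based half-open template coordinates),
#'   length, sequence.
#' @export
in_silico_pcr <- function(template, forward, reverse, max_len = 5000L) {
  if (nchar(forward) < 15L || nchar(reverse) < 15L)
    stop("primers must be at least 15 nt")
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0))
  f_pos <- find_exact(template, forward)            # 1-based starts
  r_pos <- find_exact(template, revcomp(reverse))
  if (!length(f_pos) || !length(r_pos)) return(empty)
  out <- list()
  for (f in f_pos) {
    for (r in r_pos) {
      if (r < f) next
      end <- r + nchar(reverse) - 1L                 # 1-based inclusive end
      len <- end - f + 1L
      if (len < max(nchar(forward), nchar(reverse)) || len > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        start = f - 1L, end = end, length = len,
        sequence = substring(template, f, end))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$length, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restriction digestion of an amplicon
#'
#' Cuts at every (non-overlapping) occurrence of the enzyme's recognition
#' site; fragment lengths are reported in order along the amplicon and
#' always sum to the amplicon length. An amplicon without the site yields a
#' single fragment.
#'
#' @param amplicon Character scalar, the amplicon sequence.
#' @param enzyme Enzyme name; built-ins are `"NdeI"` and `"SpeI"`.
#' @param enzymes Enzyme table (extensible): named list of
#'   `list(site=, cut=)` entries with `cut` the 0-based offset of the cut
#'   within the site.
#' @return List: enzyme, site, cut positions (0-based), fragment lengths.
#' @export
digest <- function(amplicon, enzyme, enzymes = RESTRICTION_ENZYMES) {
  if (!enzyme %in% names(enzymes))
    stop("unknown enzyme: ", enzyme)
  e <- enzymes[[enzyme]]
  sites <- find_exact(amplicon, e$site)              # 1-based starts
  cuts <- sort((sites - 1L) + e$cut)                 # 0-based cut offsets
  len <- nchar(amplicon)
  fragments <- diff(c(0L, cuts, len))
  list(enzyme = enzyme, site = e$site, cuts = cuts,
       fragments = as.integer(fragments))
}

# ---------------------------------------------------------------------------
# junction RT-PCR

#' Design exon-junction RT-PCR primer pairs for a gene model
#'
#' For each exon-exon junction i, the forward primer spans the junction (the
#' last `a` bases of exon i followed by the first `b` bases of exon i+1) and
#' the reverse primer lies entirely within exon i+1. On a normally spliced
#' transcript the pair yields a product of fixed, model-predicted length;
#' retention of intron i abolishes the forward primer's binding site and
#' hence the product.
#'
#' @param model Gene model.
#' @param reference Reference sequence.
#' @param a,b Bases of the forward primer taken from the upstream and
#'   downstream exon (junction decomposition, recorded in the output).
#' @param rev_len Reverse primer length.
#' @param rev_gap Gap between the forward primer's downstream end and the
#'   reverse primer's binding site.
#' @return Data frame: junction, forward, reverse, a, b, expected_len.
#' @export
design_junction_primers <- function(model, reference, a = 10L, b = 10L,
                                    rev_len = 20L, rev_gap = 20L) {
  spliced <- spliced_sequence(model, reference)
  junctions <- spliced_junctions(model)
  elens <- exon_lengths(model)
  out <- list()
  for (i in seq_along(junctions)) {
    if (elens[i] < a || elens[i + 1L] < b + rev_gap + rev_len) next
    jp <- junctions[i]
    fwd <- substring(spliced, jp - a + 1L, jp + b)
    rstart <- jp + b + rev_gap                       # 0-based
    rseq <- substring(spliced, rstart + 1L, rstart + rev_len)
    out[[length(out) + 1L]] <- data.frame(
      junction = i, forward = fwd, reverse = revcomp(rseq), a = a, b = b,
      expected_len = a + b + rev_gap + rev_len)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Junction RT-PCR of a transcript
#'
#' Runs [in_silico_pcr()] for every junction primer pair against a
#' transcript and reports the observed product length (NA when no product).
#'
#' @param transcript Transcript sequence.
#' @param primers Output of [design_junction_primers()].
#' @return Data frame: junction, expected_len, observed_len.
#' @export
junction_rtpcr <- function(transcript, primers) {
  obs <- vapply(seq_len(nrow(primers)), function(i) {
    amp <- in_silico_pcr(transcript, primers$forward[i], primers$reverse[i])
    if (nrow(amp)) amp$length[1L] else NA_integer_
  }, integer(1))
  data.frame(junction = primers$junction,
             expected_len = primers$expected_len, observed_len = obs)
}

# ---------------------------------------------------------------------------
# high-resolution melting

#' Simulate a high-resolution melt curve
#'
#' Two-state logistic proxy for duplex melting: a homozygote melts as
#' `F(T) = 1 / (1 + exp((T - Tm) / s))`; a heterozygote is the equal mixture
#' of its two homoduplex curves and two heteroduplex curves displaced to
#' `Tm - d_tm`. Gaussian noise is added pointwise; the curve is
#' deterministic under a fixed seed.
#'
#' @param alleles Character vector of the two alleles of the genotype (equal
#'   values for a homozygote).
#' @param tm Named numeric vector of per-allele melting temperatures
#'   (deg C), within (70, 88).
#' @param s Logistic slope parameter (deg C).
#' @param d_tm Heteroduplex destabilisation (deg C).
#' @param noise_sd Gaussian noise SD (fluorescence units).
#' @param grid Ascending uniform temperature grid (deg C).
#' @param seed Integer seed for the noise.
#' @return Data frame: temperature, fluorescence.
#' @export
simulate_melt <- function(alleles, tm, s = 0.35, d_tm = 1.0,
                          noise_sd = 0.01, grid = seq(65, 90, by = 0.2),
                          seed = 1L) {
  stopifnot(length(alleles) == 2L)
  if (is.unsorted(grid, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  tms <- tm[alleles]
  if (anyNA(tms)) stop("tm must name every allele")
  if (any(tms <= 70 | tms >= 88)) stop("allele Tm values must lie in (70, 88)")
  logistic <- function(t0) 1 / (1 + exp((grid - t0) / s))
  f <- if (alleles[1] == alleles[2]) {
    logistic(tms[1])
  } else {  # homoduplexes + destabilised heteroduplexes, equal mixture
    (logistic(tms[1]) + logistic(tms[2]) +
     logistic(tms[1] - d_tm) + logistic(tms[2] - d_tm)) / 4
  }
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(length(grid), 0, noise_sd)) else 0
  data.frame(temperature = grid, fluorescence = f + noise)
}

#' Normalize a melt curve between pre- and post-melt baselines
#'
#' Straight lines are fitted to the fluorescence in the pre-melt and
#' post-melt temperature windows; the curve is rescaled to the fraction of
#' signal between the two baselines and clipped to [-0.05, 1.05]. This is
#' affine-invariant: scaling and offsetting the raw curve leaves the
#' normalized curve unchanged.
#'
#' @param curve Data frame with `temperature` and `fluorescence`.
#' @param pre_window,post_window Length-2 temperature intervals at the ends
#'   of the grid; each must contain at least 3 points. The defaults span
#'   7 deg C so that the fitted baselines extrapolate stably across the
#'   melt region (narrow end windows amplify fluorescence noise several-fold
#'   at mid-curve temperatures).
#' @return Data frame: temperature, fluorescence (normalized).
#' @export
normalize_melt <- function(curve, pre_window = c(65, 72),
                           post_window = c(83, 90)) {
  t <- curve$temperature; f <- curve$fluorescence
  pre <- t >= pre_window[1] & t <= pre_window[2]
  post <- t >= post_window[1] & t <= post_window[2]
  if (sum(pre) < 3L || sum(post) < 3L)
    stop("baseline windows must each contain at least 3 points")
  fit_pre <- stats::lm.fit(cbind(1, t[pre]), f[pre])$coefficients
  fit_post <- stats::lm.fit(cbind(1, t[post]), f[post])$coefficients
  top <- fit_pre[1] + fit_pre[2] * t
  bottom <- fit_post[1] + fit_post[2] * t
  denom <- top - bottom
  if (any(abs(denom) < 1e-6))
    stop("degenerate curve: pre- and post-melt baselines coincide")
  out <- (f - bottom) / denom
  data.frame(temperature = t,
             fluorescence = pmin(pmax(out, -0.05), 1.05))
}

#' Cluster normalized melt curves into genotype calls
#'
#' Reference samples of known genotype seed the clusters (their centroid is
#' the mean reference curve); every sample joins the nearest centroid by the
#' maximum absolute difference between its curve and the centroid, or forms
#' a singleton cluster when no centroid is nearer than `d`. When the known
#' sex of samples is supplied, a per-sex concordance percentage is reported:
#' the share of known-sex samples assigned to the cluster seeded by their
#' own sex. Sexes whose marker alleles coincide (e.g. M and H at a
#' female-type marker) share a seed cluster and are pooled downstream.
#'
#' @param curves Numeric matrix of normalized fluorescence, one row per
#'   sample (rownames are sample ids), columns along the temperature grid.
#' @param reference Named character vector: sample id -> cluster label, for
#'   the reference samples seeding the clusters.
#' @param d Distance threshold beyond which a sample becomes a singleton.
#' @param known_sex Optional named character vector: sample id -> sex.
#' @param smooth Width (odd number of grid points) of the moving-average
#'   smoother applied to each curve before distances are computed; 1
#'   disables smoothing. Smoothing suppresses pointwise fluorescence noise
#'   without displacing the (smooth) genotype signal.
#' @return List: `calls` (data frame sample_id, cluster, distance),
#'   `correlation` (named percentage per sex, when `known_sex` given),
#'   `cluster_counts` (table of assigned samples per cluster).
#' @export
cluster_melt <- function(curves, reference, d = 0.05, known_sex = NULL,
                         smooth = 5L) {
  if (is.null(reference) || !length(reference))
    stop("at least one reference sample per expected cluster is required")
  stopifnot(is.matrix(curves), !is.null(rownames(curves)))
  if (!all(names(reference) %in% rownames(curves)))
    stop("reference sample ids missing from the curve matrix")
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    curves <- t(apply(curves, 1L, function(x)
      stats::filter(c(rep(x[1], smooth %/% 2), x,
                      rep(x[length(x)], smooth %/% 2)),
                    k)[(smooth %/% 2 + 1):(smooth %/% 2 + length(x))]))
  }
  labels <- sort(unique(reference))
  centroids <- t(vapply(labels, function(l) {
    ids <- names(reference)[reference == l]
    colMeans(curves[ids, , drop = FALSE])
  }, numeric(ncol(curves))))
  ids <- sort(rownames(curves))   # order-invariant assignment
  calls <- do.call(rbind, lapply(ids, function(id) {
    dist <- apply(centroids, 1L, function(c) max(abs(curves[id, ] - c)))
    j <- which.min(dist)
    if (dist[j] < d)
      data.frame(sample_id = id, cluster = labels[j], distance = dist[j])
    else
      data.frame(sample_id = id, cluster = paste0("singleton_", id),
                 distance = dist[j])
  }))
  rownames(calls) <- NULL
  correlation <- NULL
  if (!is.null(known_sex) && length(known_sex)) {
    sex_cluster <- lapply(split(reference, known_sex[names(reference)]),
                          unique)
    correlation <- vapply(names(sex_cluster), function(s) {
      samp <- names(known_sex)[known_sex == s]
      samp <- intersect(samp, calls$sample_id)
      if (!length(samp)) return(NA_real_)
      assigned <- calls$cluster[match(samp, calls$sample_id)]
      100 * mean(assigned %in% sex_cluster[[s]])
    }, numeric(1))
  }
  list(calls = calls, correlation = correlation,
       cluster_counts = table(calls$cluster))
}
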