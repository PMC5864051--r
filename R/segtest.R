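# Chi-squared goodness of fit of observed sex-class counts against expected
# Mendelian segregation ratios, with the pooling induced by the marker class.

CRITICAL_CHI2 <- c(`1` = 3.841, `2` = 5.991)

#' Pool per-sex counts according to the marker class
#'
#' A three-sex marker distinguishes F, H and M (expected 1:1:1 from a
#' hermaphrodite-by-male cross). A female-type marker has an X-specific
#' allele, so M and H are indistinguishable and pool against F (1:2). A
#' male-type marker has a Ym-specific allele, so F and H pool against M
#' (2:1).
#'
#' @param counts Named numeric vector with elements `F`, `H`, `M`.
#' @param marker_class One of `"THREE_SEX"`, `"FEMALE_TYPE"`, `"MALE_TYPE"`.
#' @return A `seg_observation`: list with `labels`, `observed`, `ratio`.
#' @examples
#' pool_counts(c(F = 42, H = 30, M = 24), "FEMALE_TYPE")
#' @export
pool_counts <- function(counts, marker_class) {
  stopifnot(all(c("F", "H", "M") %in% names(counts)))
  counts <- counts[c("F", "H", "M")]
  if (sum(counts) < 1) stop("no observations to pool")
  obs <- switch(marker_class,
    THREE_SEX = list(labels = c("F", "H", "M"),
                     observed = unname(counts), ratio = c(1, 1, 1)),
    FEMALE_TYPE = list(labels = c("F", "M+H"),
                       observed = unname(c(counts["F"],
                                           counts["M"] + counts["H"])),
                       ratio = c(1, 2)),
    MALE_TYPE = list(labels = c("F+H", "M"),
                     observed = unname(c(counts["F"] + counts["H"],
                                         counts["M"])),
                     ratio = c(2, 1)),
    stop("unknown marker class: ", marker_class))
  structure(obs, class = "seg_observation")
}

#' Segregation observation
#'
#' Constructor for an observed-count / expected-ratio pair used by
#' [chi_square_gof()].
#'
#' @param observed Non-negative counts (length >= 2, sum >= 1).
#' @param ratio Positive expected-ratio integers, same length.
#' @param labels Optional class labels.
#' @return A `seg_observation` list.
#' @export
seg_observation <- function(observed, ratio, labels = NULL) {
  if (length(observed) != length(ratio) || length(observed) < 2L)
    stop("observed and ratio must have equal length >= 2")
  if (any(observed < 0) || sum(observed) < 1)
    stop("observed counts must be non-negative with a positive total")
  if (any(ratio <= 0)) stop("expected ratios must be positive")
  structure(list(labels = labels %||% as.character(seq_along(observed)),
                 observed = as.numeric(observed), ratio = as.numeric(ratio)),
            class = "seg_observation")
}

#' Chi-squared goodness of fit against a segregation ratio
#'
#' Pearson's statistic without continuity correction,
#' `chi2 = sum (O - E)^2 / E` with `E = sum(O) * r / sum(r)`. Significance
#' is judged at alpha = 0.05 against the critical value (3.841 for one
#' degree of freedom, 5.991 for two; the chi-squared quantile otherwise).
#' The statistic is also reported rounded half-up to two decimals, the
#' display convention for segregation tables.
#'
#' @param obs A `seg_observation` (see [pool_counts()], [seg_observation()]),
#'   or a numeric vector of counts when `ratio` is supplied.
#' @param ratio Expected ratio (only when `obs` is a bare numeric vector).
#' @return A `seg_result` list: labels, observed, ratio, expected, chi2,
#'   chi2_rounded, df, p_value, critical, significant.
#' @examples
#' chi_square_gof(seg_observation(c(42, 54), c(1, 2)))
#' @export
chi_square_gof <- function(obs, ratio = NULL) {
  if (!inherits(obs, "seg_observation")) obs <- seg_observation(obs, ratio)
  O <- obs$observed
  r <- obs$ratio
  E <- sum(O) * r / sum(r)
  if (any(E == 0)) stop("expected count of zero")
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  crit <- if (df <= 2L) CRITICAL_CHI2[[as.character(df)]] else
    stats::qchisq(0.95, df)
  structure(list(labels = obs$labels, observed = O, ratio = r, expected = E,
                 chi2 = chi2, chi2_rounded = round_half_up(chi2, 2),
                 df = df, p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 critical = crit, significant = chi2 > crit),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("chi-squared segregation test (ratio %s)\n",
              paste(x$ratio, collapse = ":")))
  cat(sprintf("  observed: %s\n",
              paste(sprintf("%s=%g", x$labels, x$observed), collapse = ", ")))
  cat(sprintf("  chi2 = %.2f (df = %d), p = %.4g%s\n", x$chi2_rounded, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Segregation tests for a progeny panel over a marker table
#'
#' Counts the per-sex classes of a progeny table (as produced by
#' [generate_progeny()]), pools them per marker class and runs the
#' chi-squared test.
#'
#' @param progeny Progeny data frame with a `phenotype` column.
#' @param markers Marker table with `marker` and `class` columns.
#' @return Data frame: marker, class, observed (collapsed), ratio, chi2,
#'   df, significant.
#' @export
segregation_table <- function(progeny, markers) {
  counts <- c(F = sum(progeny$phenotype == "F"),
              H = sum(progeny$phenotype == "H"),
              M = sum(progeny$phenotype == "M"))
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    res <- chi_square_gof(pool_counts(counts, markers$class[i]))
    data.frame(marker = markers$marker[i], class = markers$class[i],
               observed = paste(sprintf("%s=%g", res$labels, res$observed),
                                collapse = ","),
               ratio = paste(res$ratio, collapse = ":"),
               chi2 = res$chi2_rounded, df = res$df,
               significant = res$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
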