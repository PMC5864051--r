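# Integration of per-locus expression class, splicing flag and SNP genotype
# class into flower sex-type calls and the stable-hermaphrodite rule.

FLOWER_LOCI <- c("CpSERK", "CpSVPL", "CpCAF1AL")

#' Flower-type rule table
#'
#' The rule table mapping third-/fourth-whorl locus profiles (expression
#' class and splicing flag at CpSERK, CpSVPL and CpCAF1AL, in that order,
#' plus the SNP genotype class) to flower sex types: male (M), normal
#' hermaphrodite (H), female-sterile hermaphrodite (HM), carpellate
#' hermaphrodite (HF), and the fourth-whorl female profile. The table is
#' data, not code, so additional loci or species rules can be loaded.
#'
#' @return Data frame, one rule per row.
#' @export
flower_rule_table <- function() {
  data.frame(
    call = c("M", "H", "HM", "HF", "F_fourth_whorl"),
    whorl = c("third", "third", "third", "third", "fourth"),
    CpSERK_expr = c("NOVAR", "NOVAR", "NOVAR", "NOVAR", "NOVAR"),
    CpSERK_as = c("NO_AS", "NO_AS", "AS", "AS", "AS"),
    CpSVPL_expr = c("HIGH", "LOW", "HIGH", "LOW", "LOW"),
    CpSVPL_as = c("NO_AS", "NO_AS", "NO_AS", "NO_AS", "NO_AS"),
    CpCAF1AL_expr = c("HIGH", "HIGH", "LOW", "LOW", "LOW"),
    CpCAF1AL_as = c("NO_AS", "NO_AS", "AS", "AS", "AS"),
    genotype = c("XYm", "XYh", "XYh", "XYh", "XX"))
}

#' Classify relative expression against a panel
#'
#' A value at least `high` times the panel median is HIGH, at most `low`
#' times the median is LOW, NOVAR otherwise. The panel is the set of
#' housekeeping-normalized relative expression values the value is judged
#' against (in the pipeline, all locus/sample values of the cohort, whose
#' median sits at the unchanged-expression baseline).
#'
#' @param value Numeric vector of values to classify.
#' @param panel Numeric vector of panel values (>= 3, not all zero).
#' @param high,low Thresholds as multiples of the panel median.
#' @return Character vector in `HIGH`, `LOW`, `NOVAR`.
#' @export
classify_expression <- function(value, panel, high = 2, low = 0.5) {
  if (length(panel) < 3L) stop("panel median needs at least 3 samples")
  med <- stats::median(panel)
  if (med == 0) stop("all-zero expression panel")
  ifelse(value >= high * med, "HIGH",
         ifelse(value <= low * med, "LOW", "NOVAR"))
}

#' Derive the splicing flag from junction RT-PCR products
#'
#' A locus is flagged AS when any junction assay yields no product or a
#' product whose length differs from the model prediction by more than
#' `tol` bp; NO_AS otherwise.
#'
#' @param products Data frame with `expected_len` and `observed_len`
#'   (NA = no product), one row per junction (see [junction_rtpcr()]).
#' @param tol Length tolerance in bp.
#' @return `"AS"` or `"NO_AS"`.
#' @export
derive_as_flag <- function(products, tol = 5L) {
  if (is.null(products) || !nrow(products))
    stop("no junction assays defined for this locus")
  bad <- is.na(products$observed_len) |
    abs(products$observed_len - products$expected_len) > tol
  if (any(bad)) "AS" else "NO_AS"
}

# A locus profile is a named list over FLOWER_LOCI of
# list(expr =, as =, genotype =).
check_profile <- function(profile) {
  if (!all(FLOWER_LOCI %in% names(profile)))
    stop("profile must cover loci: ", paste(FLOWER_LOCI, collapse = ", "))
  invisible(profile)
}

#' Predict the flower sex type from a locus profile
#'
#' Matches the per-locus (expression class, splicing flag) triple and the
#' SNP genotype class against the rule table for the given whorl; exactly
#' one rule matches or the call is UNKNOWN. The genotype used for rule
#' matching is the one observed at the CpSVPL locus, whose three-sex marker
#' resolves all three chromosome classes.
#'
#' @param profile Named list over `CpSERK`, `CpSVPL`, `CpCAF1AL`, each a
#'   list with `expr` (HIGH/LOW/NOVAR), `as` (AS/NO_AS) and `genotype`
#'   (XX/XYm/XYh).
#' @param whorl `"third"` or `"fourth"`.
#' @param rules Rule table (default [flower_rule_table()]).
#' @return List: `call` (M, H, HM, HF, F_fourth_whorl or UNKNOWN) and
#'   `rule` (matched rule id or NA).
#' @export
predict_flower_type <- function(profile, whorl = "third",
                                rules = flower_rule_table()) {
  check_profile(profile)
  genotype <- profile$CpSVPL$genotype
  match_rule <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    r$whorl == whorl && r$genotype == genotype &&
      all(vapply(FLOWER_LOCI, function(l)
        identical(profile[[l]]$expr, r[[paste0(l, "_expr")]]) &&
        identical(profile[[l]]$as, r[[paste0(l, "_as")]]), logical(1)))
  }, logical(1))
  if (sum(match_rule) == 1L) {
    i <- which(match_rule)
    list(call = rules$call[i], rule = i)
  } else {
    list(call = "UNKNOWN", rule = NA_integer_)
  }
}

#' Stable-hermaphrodite call
#'
#' Evaluable only for a profile predicted as a normal hermaphrodite (H);
#' calling it on any other profile is an error. A hermaphrodite is called
#' stable when, with the H expression/splicing pattern, the CpSERK locus
#' does not carry the female (XX) genotype class, the CpSVPL locus carries
#' the XYh genotype, and the CpCAF1AL locus does not carry the male (XYm)
#' genotype.
#'
#' @inheritParams predict_flower_type
#' @return Logical flag.
#' @export
call_stable_hermaphrodite <- function(profile, whorl = "third",
                                      rules = flower_rule_table()) {
  check_profile(profile)
  pred <- predict_flower_type(profile, whorl, rules)
  if (!identical(pred$call, "H"))
    stop("stable-hermaphrodite call is only defined for profiles ",
         "predicted as H (got ", pred$call, ")")
  profile$CpSERK$genotype != "XX" &&
    profile$CpSVPL$genotype == "XYh" &&
    profile$CpCAF1AL$genotype != "XYm"
}

#' Render a functional-map table
#'
#' Lays the rule table (or a set of per-sample calls) out as the compact
#' per-locus map used to summarise sex types: one row per flower type, one
#' column per locus holding "expression/AS flag", plus the genotype class.
#'
#' @param rules Rule table.
#' @return Data frame.
#' @export
functional_map_table <- function(rules = flower_rule_table()) {
  out <- data.frame(flower_type = rules$call, whorl = rules$whorl)
  for (l in FLOWER_LOCI) {
    out[[l]] <- paste0(tolower(rules[[paste0(l, "_expr")]]), "/",
                       ifelse(rules[[paste0(l, "_as")]] == "AS",
                              "AS-seq", "no AS-seq"))
  }
  out$genotype <- rules$genotype
  out
}
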