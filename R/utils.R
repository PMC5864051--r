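# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go
# through this so that results are reproducible and independent of the
# caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a component sub-seed from a root seed so that adding a component
# does not perturb the streams of the others. Kept below 2^31 - 1.
sub_seed <- function(seed, component) {
  (as.double(seed) * 48271 + component * 16807) %% 2147483647
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Standard-code translation of an in-frame nucleotide string; trailing
# partial codon ignored. Stops are translated as "*".
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq_len(n) * 3L - 2L, seq_len(n) * 3L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Translate until (and excluding) the first stop codon; returns the protein
# and the 1-based codon index of the first stop (NA when none found).
translate_to_stop <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(list(aa = "", stop_codon = NA_integer_))
  codons <- substring(nt, seq_len(n) * 3L - 2L, seq_len(n) * 3L)
  stop_at <- which(codons %in% STOP_CODONS)
  if (length(stop_at)) {
    first <- stop_at[1L]
    aa <- if (first > 1L) Biostrings::GENETIC_CODE[codons[seq_len(first - 1L)]] else character(0)
    list(aa = paste(aa, collapse = ""), stop_codon = first)
  } else {
    list(aa = paste(Biostrings::GENETIC_CODE[codons], collapse = ""), stop_codon = NA_integer_)
  }
}

# Round half away from zero to `digits` decimals (display convention for
# reported chi-squared statistics).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
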