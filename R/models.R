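# Gene-model helpers. A gene model is a plain list:
#   gene_id, reference_id, strand, exons (data.frame start/end, 0-based
#   half-open genomic), cds_start/cds_end (0-based half-open coordinates on
#   the spliced transcript).
# All internal coordinates are 0-based half-open; GFF3 output converts to
# 1-based inclusive.

gene_model <- function(gene_id, reference_id, exons, cds_start, cds_end,
                       strand = "+") {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end - exons$start < 1L))
    stop("each exon must be at least 1 bp")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping and sorted")
  sl <- sum(exons$end - exons$start)
  if (cds_start < 0L || cds_end > sl || cds_start >= cds_end)
    stop("cds interval must lie within the spliced length")
  structure(list(gene_id = gene_id, reference_id = reference_id,
                 strand = strand, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "gene_model")
}

exon_lengths <- function(model) model$exons$end - model$exons$start

spliced_length <- function(model) sum(exon_lengths(model))

gene_span <- function(model) c(model$exons$start[1L],
                               model$exons$end[nrow(model$exons)])

# 0-based spliced positions of the exon-exon junctions (position just after
# the last base of exon i, i = 1..n-1).
spliced_junctions <- function(model) {
  cs <- cumsum(exon_lengths(model))
  cs[-length(cs)]
}

# 0-based spliced start of each exon.
spliced_exon_starts <- function(model) {
  c(0L, cumsum(exon_lengths(model)))[seq_len(nrow(model$exons))]
}

exon_sequences <- function(model, ref_seq) {
  substring(ref_seq, model$exons$start + 1L, model$exons$end)
}

intron_sequences <- function(model, ref_seq) {
  n <- nrow(model$exons)
  if (n < 2L) return(character(0))
  substring(ref_seq, model$exons$end[-n] + 1L, model$exons$start[-1L])
}

intron_lengths <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) return(integer(0))
  model$exons$start[-1L] - model$exons$end[-n]
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates the exon sequences of `model` on the plus strand of the
#' reference (minus-strand models are reverse-complemented).
#'
#' @param model A gene model as produced by [generate_dataset()].
#' @param ref_seq Character scalar, the reference region sequence.
#' @return A character scalar.
#' @export
spliced_sequence <- function(model, ref_seq) {
  s <- paste(exon_sequences(model, ref_seq), collapse = "")
  if (identical(model$strand, "-")) revcomp(s) else s
}

# Genomic (unspliced) sequence across the gene span.
gene_sequence <- function(model, ref_seq) {
  sp <- gene_span(model)
  s <- substring(ref_seq, sp[1L] + 1L, sp[2L])
  if (identical(model$strand, "-")) revcomp(s) else s
}

# Map the spliced CDS interval to genomic intervals (0-based half-open),
# used when exporting CDS features.
cds_genomic_intervals <- function(model) {
  lens <- exon_lengths(model)
  starts_sp <- spliced_exon_starts(model)
  out <- list()
  for (i in seq_len(nrow(model$exons))) {
    lo <- max(model$cds_start, starts_sp[i])
    hi <- min(model$cds_end, starts_sp[i] + lens[i])
    if (lo < hi) {
      off <- model$exons$start[i] - starts_sp[i]
      out[[length(out) + 1L]] <- c(lo + off, hi + off)
    }
  }
  do.call(rbind, out)
}
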