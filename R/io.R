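# External interchange: FASTA for references and transcripts, GFF3 for gene
# models (1-based inclusive on output), CSV for the ledger, expression,
# marker and progeny tables.

transcript_ids <- function(transcripts) {
  paste(transcripts$gene_id, transcripts$sex_type, transcripts$whorl,
        sep = "|")
}

models_to_granges <- function(models) {
  rows <- list()
  for (m in models) {
    sp <- gene_span(m)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = m$reference_id, start = sp[1] + 1L, end = sp[2],
      type = "gene", ID = m$gene_id, Parent = NA_character_)
    for (i in seq_len(nrow(m$exons)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$reference_id, start = m$exons$start[i] + 1L,
        end = m$exons$end[i], type = "exon",
        ID = paste0(m$gene_id, ":exon", i), Parent = m$gene_id)
    cds <- cds_genomic_intervals(m)
    for (i in seq_len(nrow(cds)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$reference_id, start = cds[i, 1] + 1L, end = cds[i, 2],
        type = "CDS", ID = paste0(m$gene_id, ":cds", i), Parent = m$gene_id)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+")
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- df$Parent
  gr$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  gr
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes `references.fasta` and `transcripts.fasta` (80-character lines),
#' `models.gff3` (1-based inclusive gene/exon/CDS features),
#' `ledger.csv`, `expression.csv`, `markers.csv`, `progeny.csv` and
#' `truth.csv`.
#'
#' @param bundle A [generate_dataset()] bundle.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  refs <- Biostrings::DNAStringSet(bundle$references)
  Biostrings::writeXStringSet(refs, file.path(dir, "references.fasta"),
                              width = 80L)
  tx <- bundle$transcripts[bundle$transcripts$present, , drop = FALSE]
  txs <- Biostrings::DNAStringSet(tx$sequence)
  names(txs) <- transcript_ids(tx)
  Biostrings::writeXStringSet(txs, file.path(dir, "transcripts.fasta"),
                              width = 80L)
  gr <- models_to_granges(bundle$models)
  rtracklayer::export(gr, file.path(dir, "models.gff3"), format = "gff3")
  utils::write.csv(bundle$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$transcripts[, c("gene_id", "sex_type", "whorl",
                                          "present", "expression")],
                   file.path(dir, "expression.csv"), row.names = FALSE)
  utils::write.csv(bundle$markers, file.path(dir, "markers.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$progeny, file.path(dir, "progeny.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read gene models from a GFF3 file
#'
#' Reconstructs the internal gene-model list (0-based half-open
#' coordinates) from gene/exon/CDS features written by [write_dataset()].
#'
#' @param path GFF3 file.
#' @return Named list of gene models.
#' @export
read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  models <- list()
  for (i in seq_along(genes)) {
    gid <- genes$ID[i]
    parent <- as.character(gr$Parent)
    ex <- gr[gr$type == "exon" & !is.na(parent) & parent == gid]
    cds <- gr[gr$type == "CDS" & !is.na(parent) & parent == gid]
    exons <- data.frame(start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
    exons <- exons[order(exons$start), , drop = FALSE]
    # CDS interval back to spliced coordinates
    lens <- exons$end - exons$start
    starts_sp <- c(0L, cumsum(lens))[seq_len(nrow(exons))]
    cds_g <- c(min(GenomicRanges::start(cds)) - 1L,
               max(GenomicRanges::end(cds)))
    to_spliced <- function(g) {
      i <- which(exons$start <= g & g <= exons$end)[1L]
      starts_sp[i] + (g - exons$start[i])
    }
    models[[gid]] <- gene_model(
      gid, as.character(GenomicRanges::seqnames(genes)[i]), exons,
      cds_start = to_spliced(cds_g[1]), cds_end = to_spliced(cds_g[2]))
  }
  models
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}
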