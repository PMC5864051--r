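# Transcript-to-reference functional mapping: assign sex-typed transcripts
# to gene models, build the per-gene presence table across sex types, and
# apply the candidate-gene filters.

.trisex_cache <- new.env(parent = emptyenv())

align_matrix <- function() {
  m <- .trisex_cache$subst
  if (is.null(m)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
    .trisex_cache$subst <- m
  }
  m
}

# Global alignment with affine gaps (match 2, mismatch -3, open -6,
# extend -1); shared by the mapper and the splice-event caller.
align_pair <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    substitutionMatrix = align_matrix(),
    gapOpening = 6, gapExtension = 1, type = "global")
}

# identity over aligned (gap-free) columns; coverage = fraction of the
# transcript aligned to reference bases
alignment_stats <- function(aln, pattern_len) {
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  list(identity = if (nm + nmm > 0) nm / (nm + nmm) else 0,
       coverage = (nm + nmm) / pattern_len)
}

kmer_set <- function(seq, k = 15L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Map transcripts onto reference gene models
#'
#' Seed-and-extend mapping at desk scale: a transcript is a candidate for a
#' gene when the two share an exact 15-mer; candidates are then aligned
#' globally (affine gaps) against the gene's genomic span, so spliced
#' transcripts align with intron-sized deletions and intron-retaining
#' transcripts remain fully covered. Each transcript is assigned to at most
#' one best gene by identity x coverage (ties broken by lowest reference id,
#' then lowest gene coordinate); hits below either threshold are discarded.
#'
#' @param transcripts Data frame with columns `transcript_id` and `sequence`.
#' @param references Named character vector of reference sequences.
#' @param models Named list of gene models.
#' @param min_identity,min_coverage Acceptance thresholds in (0, 1].
#' @param k Seed k-mer length.
#' @return Data frame of hits: transcript_id, reference_id, gene_id,
#'   identity, coverage, score, ref_start, ref_end (0-based half-open
#'   alignment span on the reference).
#' @export
map_transcripts <- function(transcripts, references, models,
                            min_identity = 0.95, min_coverage = 0.90,
                            k = 15L) {
  if (length(references) == 0L) stop("empty reference set")
  stopifnot(all(c("transcript_id", "sequence") %in% names(transcripts)))
  if (any(min_identity <= 0, min_identity > 1, min_coverage <= 0,
          min_coverage > 1))
    stop("thresholds must lie in (0, 1]")

  gene_ids <- names(models)
  gene_seqs <- vapply(gene_ids, function(g)
    gene_sequence(models[[g]], references[[models[[g]]$reference_id]]),
    character(1))
  gene_kmers <- lapply(gene_seqs, kmer_set, k = k)
  gene_start <- vapply(gene_ids, function(g) models[[g]]$exons$start[1L], 0)
  gene_ref <- vapply(gene_ids, function(g) models[[g]]$reference_id, "")

  # sort transcripts so mapping is independent of input order
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]

  hits <- list()
  for (t in seq_len(nrow(transcripts))) {
    tseq <- transcripts$sequence[t]
    if (is.na(tseq) || !nzchar(tseq)) next
    tkmers <- kmer_set(tseq, k = k)
    cand <- gene_ids[vapply(gene_kmers, function(ks)
      any(tkmers %in% ks), logical(1))]
    if (!length(cand)) next
    best <- NULL
    for (g in cand) {
      aln <- align_pair(tseq, gene_seqs[[g]])
      st <- alignment_stats(aln, nchar(tseq))
      score <- st$identity * st$coverage
      rec <- list(gene = g, identity = st$identity, coverage = st$coverage,
                  score = score, aln = aln)
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (gene_ref[g] < gene_ref[best$gene] ||
            (gene_ref[g] == gene_ref[best$gene] &&
             gene_start[g] < gene_start[best$gene]))))
        best <- rec
    }
    if (best$identity >= min_identity && best$coverage >= min_coverage) {
      g <- best$gene
      sub_rng <- range(which(strsplit(as.character(
        Biostrings::alignedSubject(best$aln)), "")[[1]] != "-"))
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = transcripts$transcript_id[t],
        reference_id = gene_ref[[g]], gene_id = g,
        identity = best$identity, coverage = best$coverage,
        score = best$score,
        ref_start = gene_start[[g]],
        ref_end = gene_start[[g]] + nchar(gene_seqs[[g]]))
    }
  }
  if (!length(hits))
    return(data.frame(transcript_id = character(0),
                      reference_id = character(0), gene_id = character(0),
                      identity = double(0), coverage = double(0),
                      score = double(0), ref_start = double(0),
                      ref_end = double(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Per-gene, per-sex-type presence table
#'
#' Presence of a sex type at a gene is the OR over that sex type's mapped
#' transcripts. The table covers every gene of every model, including genes
#' with no hits.
#'
#' @param hits Output of [map_transcripts()].
#' @param models Named list of gene models.
#' @param transcript_sex Named character vector mapping transcript ids to a
#'   sex type in `F`, `M`, `H` (transcripts of other labels are ignored).
#' @return Data frame: reference_id, gene_id, F, M, H (logical), n_sexes;
#'   with an attribute `k_counts` giving the number of genes present in
#'   exactly 1, 2 and 3 sex types.
#' @export
build_presence_table <- function(hits, models, transcript_sex) {
  gene_ids <- names(models)
  tab <- data.frame(
    reference_id = vapply(models, function(m) m$reference_id, ""),
    gene_id = gene_ids,
    F = FALSE, M = FALSE, H = FALSE)
  if (nrow(hits)) {
    sex <- transcript_sex[hits$transcript_id]
    for (s in c("F", "M", "H")) {
      present_genes <- unique(hits$gene_id[!is.na(sex) & sex == s])
      tab[[s]] <- tab$gene_id %in% present_genes
    }
  }
  tab$n_sexes <- tab$F + tab$M + tab$H
  attr(tab, "k_counts") <- c(`1` = sum(tab$n_sexes == 1L),
                             `2` = sum(tab$n_sexes == 2L),
                             `3` = sum(tab$n_sexes == 3L))
  rownames(tab) <- NULL
  tab
}

#' Candidate-gene selection rules
#'
#' Two nested screening filters: `NOT_F_BUT_MH` keeps genes with no
#' expression in females but expression in both males and hermaphrodites;
#' `TWO_OR_THREE_SEXES` keeps genes expressed in at least two of the three
#' sex types.
#'
#' @param table A presence table from [build_presence_table()].
#' @param rule `"NOT_F_BUT_MH"` or `"TWO_OR_THREE_SEXES"`.
#' @param models Named list of gene models (for coordinate-sorted output).
#' @return Character vector of gene ids sorted by (reference_id, gene
#'   coordinate).
#' @export
select_candidate_genes <- function(table, rule, models) {
  keep <- switch(rule,
    NOT_F_BUT_MH = !table$F & table$M & table$H,
    TWO_OR_THREE_SEXES = table$n_sexes >= 2L,
    stop("unknown rule: ", rule))
  sel <- table[keep, , drop = FALSE]
  start <- vapply(sel$gene_id, function(g) models[[g]]$exons$start[1L], 0)
  sel$gene_id[order(sel$reference_id, start)]
}
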