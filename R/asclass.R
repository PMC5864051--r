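# Splice/coding-event calling against the gene model, and the derived
# four-category AS classification plus three sex-grouping types.

AS_CATEGORIES <- c("EXON_JUMP", "INTRON_JUMP", "AA_SHORT", "NO_CHANGE")
SEX_GROUP_TYPES <- c("TYPE_1", "TYPE_2", "TYPE_3", "NONE")

# Parse a global pairwise alignment into column-level differences on the
# subject (spliced-model) coordinate system. Returns insertions (transcript
# sequence absent from the model), deletions (model sequence absent from the
# transcript) and substitutions, with 0-based subject positions.
parse_alignment <- function(aln) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n <- length(pat)
  ins <- list(); del <- list(); subst <- list()
  spos <- 0L
  i <- 1L
  while (i <= n) {
    if (sub[i] == "-") {            # insertion relative to the model
      j <- i
      while (j <= n && sub[j] == "-") j <- j + 1L
      ins[[length(ins) + 1L]] <- list(
        pos = spos, seq = paste(pat[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (pat[i] == "-") {     # deletion of model sequence
      j <- i
      while (j <= n && pat[j] == "-") j <- j + 1L
      del[[length(del) + 1L]] <- list(pos = spos, len = j - i)
      spos <- spos + (j - i)
      i <- j
    } else {
      if (pat[i] != sub[i])
        subst[[length(subst) + 1L]] <- list(pos = spos, ref = sub[i],
                                            alt = pat[i])
      spos <- spos + 1L
      i <- i + 1L
    }
  }
  list(insertions = ins, deletions = del, substitutions = subst)
}

# Indel placement is ambiguous wherever flanking bases repeat; enumerate the
# equivalent placements and return the one closest to an annotated target
# position (ties toward the annotated site). `seq` is the inserted sequence
# (insertions) or NULL (deletions of length `len`).
normalize_indel <- function(subject_chars, pos, targets, seq = NULL,
                            len = NULL, max_shift = 60L) {
  if (!length(targets)) return(pos)
  positions <- pos
  if (!is.null(seq)) {   # insertion between subject[pos-1] and subject[pos]
    s <- strsplit(seq, "")[[1]]
    p <- pos; cur <- s
    for (step in seq_len(max_shift)) {   # shift right
      if (p + 1L > length(subject_chars) || cur[1L] != subject_chars[p + 1L]) break
      cur <- c(cur[-1L], subject_chars[p + 1L]); p <- p + 1L
      positions <- c(positions, p)
    }
    p <- pos; cur <- s
    for (step in seq_len(max_shift)) {   # shift left
      if (p < 1L || cur[length(cur)] != subject_chars[p]) break
      cur <- c(subject_chars[p], cur[-length(cur)]); p <- p - 1L
      positions <- c(positions, p)
    }
  } else {               # deletion of subject[pos .. pos+len-1] (0-based)
    p <- pos
    for (step in seq_len(max_shift)) {   # shift right
      e <- p + len
      if (e + 1L > length(subject_chars) ||
          subject_chars[p + 1L] != subject_chars[e + 1L]) break
      p <- p + 1L
      positions <- c(positions, p)
    }
    p <- pos
    for (step in seq_len(max_shift)) {   # shift left
      if (p < 1L || subject_chars[p] != subject_chars[p + len]) break
      p <- p - 1L
      positions <- c(positions, p)
    }
  }
  d <- vapply(positions, function(q) min(abs(q - targets)), 0)
  positions[which.min(d)]
}

#' Call splice and coding events of a transcript against its gene model
#'
#' The transcript is aligned globally (affine gaps) to the spliced model
#' sequence. A contiguous insertion whose placement (after normalising the
#' usual indel-position ambiguity toward the annotated splice sites) falls
#' within 2 bp of an exon-exon junction and whose length is within 2 bp of
#' that intron's length is called an intron retention; a deletion matching an
#' annotated exon the same way is called an exon skip. Remaining indels and
#' all mismatches are reported as substitution-class events.
#'
#' @param transcript Character scalar, the transcript sequence.
#' @param model Gene model.
#' @param reference Reference sequence the model lives on.
#' @param min_identity Identity (over aligned columns) below which the
#'   transcript is rejected as not matching the model.
#' @param slack Maximum positional/length discrepancy (bp) for matching an
#'   indel to an annotated intron or exon.
#' @return Data frame of events: type (`INTRON_RETENTION`, `EXON_SKIP`,
#'   `SUBSTITUTION`, `INDEL`), index (intron/exon index, NA otherwise),
#'   pos (0-based spliced-model position), len, detail.
#' @export
align_to_model <- function(transcript, model, reference,
                           min_identity = 0.95, slack = 2L) {
  spliced <- spliced_sequence(model, reference)
  aln <- align_pair(transcript, spliced)
  st <- alignment_stats(aln, nchar(transcript))
  if (st$identity < min_identity)
    stop("transcript does not match the gene model (identity ",
         sprintf("%.3f", st$identity), " < ", min_identity, ")")
  diffs <- parse_alignment(aln)
  sub_chars <- strsplit(spliced, "")[[1]]
  junctions <- spliced_junctions(model)
  ilens <- intron_lengths(model)
  estarts <- spliced_exon_starts(model)
  elens <- exon_lengths(model)

  ev <- list()

  # Near a substitution, the optimal alignment may split one biological
  # indel into two gap blocks bridged by a few opportunistically matched
  # columns. Candidate events are therefore raw indels plus merged runs of
  # same-type indels separated by at most `merge_gap` aligned columns.
  merge_gap <- 10L

  match_intron <- function(pos, len, seq = NULL) {
    p <- normalize_indel(sub_chars, pos, junctions, seq = seq,
                         len = if (is.null(seq)) len else NULL)
    i <- which(abs(p - junctions) <= slack & abs(len - ilens) <= slack)
    if (length(i) == 1L) i else NA_integer_
  }
  ins <- diffs$insertions
  consumed <- rep(FALSE, length(ins))
  for (x in seq_along(ins)) {
    len <- nchar(ins[[x]]$seq)
    i <- match_intron(ins[[x]]$pos, len, seq = ins[[x]]$seq)
    if (!is.na(i)) {
      consumed[x] <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(
        type = "INTRON_RETENTION", index = i, pos = junctions[i], len = len,
        detail = paste0("intron ", i))
    }
  }
  # merged runs of the remaining insertions (net inserted length summed)
  x <- 1L
  while (x <= length(ins)) {
    if (consumed[x]) { x <- x + 1L; next }
    run <- x
    while (run < length(ins) && !consumed[run + 1L] &&
           ins[[run + 1L]]$pos - ins[[run]]$pos <= merge_gap)
      run <- run + 1L
    if (run > x) {
      net <- sum(vapply(x:run, function(q) nchar(ins[[q]]$seq), 0L))
      i <- match_intron(ins[[x]]$pos, net)
      if (!is.na(i)) {
        consumed[x:run] <- TRUE
        ev[[length(ev) + 1L]] <- data.frame(
          type = "INTRON_RETENTION", index = i, pos = junctions[i],
          len = net, detail = paste0("intron ", i, " (split alignment)"))
        x <- run + 1L
        next
      }
    }
    ev[[length(ev) + 1L]] <- data.frame(
      type = "INDEL", index = NA_integer_, pos = ins[[x]]$pos,
      len = nchar(ins[[x]]$seq),
      detail = paste0("insertion +", nchar(ins[[x]]$seq), " bp"))
    consumed[x] <- TRUE
    x <- x + 1L
  }

  match_exon <- function(pos, net, span) {
    p <- normalize_indel(sub_chars, pos, estarts, len = net)
    j <- which(abs(p - estarts) <= slack &
               (abs(net - elens) <= slack | abs(span - elens) <= slack))
    if (length(j) == 1L) j else NA_integer_
  }
  del <- diffs$deletions
  consumed <- rep(FALSE, length(del))
  for (x in seq_along(del)) {
    j <- match_exon(del[[x]]$pos, del[[x]]$len, del[[x]]$len)
    if (!is.na(j)) {
      consumed[x] <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(
        type = "EXON_SKIP", index = j, pos = estarts[j], len = del[[x]]$len,
        detail = paste0("exon ", j))
    }
  }
  x <- 1L
  while (x <= length(del)) {
    if (consumed[x]) { x <- x + 1L; next }
    run <- x
    while (run < length(del) && !consumed[run + 1L] &&
           del[[run + 1L]]$pos -
             (del[[run]]$pos + del[[run]]$len) <= merge_gap)
      run <- run + 1L
    if (run > x) {
      net <- sum(vapply(x:run, function(q) del[[q]]$len, 0L))
      span <- (del[[run]]$pos + del[[run]]$len) - del[[x]]$pos
      j <- match_exon(del[[x]]$pos, net, span)
      if (!is.na(j)) {
        consumed[x:run] <- TRUE
        ev[[length(ev) + 1L]] <- data.frame(
          type = "EXON_SKIP", index = j, pos = estarts[j], len = net,
          detail = paste0("exon ", j, " (split alignment)"))
        x <- run + 1L
        next
      }
    }
    ev[[length(ev) + 1L]] <- data.frame(
      type = "INDEL", index = NA_integer_, pos = del[[x]]$pos,
      len = del[[x]]$len,
      detail = paste0("deletion -", del[[x]]$len, " bp"))
    consumed[x] <- TRUE
    x <- x + 1L
  }
  for (s in diffs$substitutions) {
    ev[[length(ev) + 1L]] <- data.frame(
      type = "SUBSTITUTION", index = NA_integer_, pos = s$pos, len = 1L,
      detail = paste0(s$ref, ">", s$alt))
  }
  if (!length(ev))
    return(data.frame(type = character(0), index = integer(0),
                      pos = integer(0), len = integer(0),
                      detail = character(0)))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Translate the coding region of a transcript
#'
#' The annotated CDS start is located on the transcript by alignment to the
#' spliced model sequence; translation proceeds in the standard code from
#' that anchor to the first stop codon (or through `floor(len/3)` codons when
#' none occurs). A stop earlier than the annotated stop codon is reported as
#' a truncation; a transcript CDS whose aligned length is not a codon
#' multiple is flagged as a frameshift.
#'
#' @inheritParams align_to_model
#' @return List: `aa` (protein up to the first stop), `stop_codon` (1-based
#'   codon index of the first stop, NA if none), `truncated`, `frameshift`,
#'   `cds_start_tx` (0-based CDS start on the transcript).
#' @export
translate_cds <- function(transcript, model, reference) {
  spliced <- spliced_sequence(model, reference)
  aln <- align_pair(transcript, spliced)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map_anchor <- function(target) {
    spos <- 0L; ppos <- 0L
    for (i in seq_along(sub)) {
      if (sub[i] != "-") {
        if (spos == target) {
          if (pat[i] == "-") return(NA_integer_)
          return(ppos)
        }
        spos <- spos + 1L
      }
      if (pat[i] != "-") ppos <- ppos + 1L
    }
    NA_integer_
  }
  start_tx <- map_anchor(model$cds_start)
  if (is.na(start_tx)) stop("CDS start anchor cannot be aligned to the transcript")
  end_tx <- map_anchor(model$cds_end - 1L)
  end_tx <- if (is.na(end_tx)) nchar(transcript) else end_tx + 1L
  tail_nt <- substring(transcript, start_tx + 1L, nchar(transcript))
  tr <- translate_to_stop(tail_nt)
  n_codons <- (model$cds_end - model$cds_start) %/% 3L
  list(aa = tr$aa, stop_codon = tr$stop_codon,
       truncated = !is.na(tr$stop_codon) && tr$stop_codon < n_codons,
       frameshift = ((end_tx - start_tx) %% 3L) != 0L,
       cds_start_tx = start_tx)
}

#' Four-category AS classification for one gene
#'
#' Categories form a partition under the precedence
#' EXON_JUMP > INTRON_JUMP > AA_SHORT > NO_CHANGE: an exon skip in any
#' sex type's transcript makes the gene EXON_JUMP; otherwise any intron
#' retention makes it INTRON_JUMP; otherwise any premature-stop truncation
#' makes it AA_SHORT; substitution-only genes are NO_CHANGE (they may still
#' differ in protein sequence, which the sex-grouping typing captures).
#'
#' @param gene_events Named list (one element per sex type with a
#'   transcript) of lists with elements `events` (from [align_to_model()])
#'   and `truncated` (from [translate_cds()]).
#' @return One of `"EXON_JUMP"`, `"INTRON_JUMP"`, `"AA_SHORT"`,
#'   `"NO_CHANGE"`.
#' @export
classify_as_category <- function(gene_events) {
  if (length(gene_events) < 2L)
    stop("gene is not comparable: fewer than two sex types have transcripts")
  types <- unlist(lapply(gene_events, function(x) x$events$type))
  if (any(types == "EXON_SKIP")) return("EXON_JUMP")
  if (any(types == "INTRON_RETENTION")) return("INTRON_JUMP")
  if (any(vapply(gene_events, function(x) isTRUE(x$truncated), logical(1))))
    return("AA_SHORT")
  "NO_CHANGE"
}

#' Sex-grouping type from presence pattern and pairwise protein identity
#'
#' `TYPE_1`: expressed in exactly two sex types whose proteins differ;
#' `TYPE_2`: expressed in all three with mutually different proteins;
#' `TYPE_3`: expressed in all three with exactly one identical pair;
#' `NONE` otherwise.
#'
#' @param present Named logical over `F`, `M`, `H`.
#' @param aa_identical Named logical of pairwise protein identity for the
#'   present pairs; names are of the form `"F:M"`, `"F:H"`, `"M:H"`.
#' @return One of `"TYPE_1"`, `"TYPE_2"`, `"TYPE_3"`, `"NONE"`.
#' @export
classify_sex_group_type <- function(present, aa_identical) {
  stopifnot(all(c("F", "M", "H") %in% names(present)))
  sexes <- names(present)[as.logical(present[c("F", "M", "H")])]
  if (length(sexes) < 2L) return("NONE")
  pair_names <- apply(utils::combn(sexes, 2L), 2L, paste, collapse = ":")
  if (!all(pair_names %in% names(aa_identical)))
    stop("aa_identical must cover all present pairs: ",
         paste(setdiff(pair_names, names(aa_identical)), collapse = ", "))
  same <- as.logical(aa_identical[pair_names])
  if (length(sexes) == 2L) return(if (!same) "TYPE_1" else "NONE")
  n_same <- sum(same)
  if (n_same == 0L) return("TYPE_2")
  if (n_same == 1L) return("TYPE_3")
  "NONE"
}

#' Run the AS classification over a labelled transcript set
#'
#' Convenience pipeline used after mapping: for every gene with transcripts
#' in at least one of the sex types F, M, H, events and translations are
#' computed per sex type and combined into the per-gene category and
#' sex-grouping type.
#'
#' @param transcripts Data frame with columns gene_id, sex_type, whorl,
#'   present, sequence (as in a [generate_dataset()] bundle).
#' @param models Named list of gene models.
#' @param references Named character vector of reference sequences.
#' @param whorl Which tissue's transcripts to use (default the 28-day buds).
#' @return Data frame: gene_id, n_sexes, category (NA for genes with fewer
#'   than two expressed sex types), sex_group_type, events (JSON).
#' @export
run_as_classification <- function(transcripts, models, references,
                                  whorl = "bud28") {
  tx <- transcripts[transcripts$whorl == whorl &
                    transcripts$sex_type %in% c("F", "M", "H") &
                    transcripts$present, , drop = FALSE]
  out <- list()
  for (gid in names(models)) {
    sub <- tx[tx$gene_id == gid, , drop = FALSE]
    if (!nrow(sub)) next
    model <- models[[gid]]
    ref <- references[[model$reference_id]]
    per_sex <- list(); aa <- list()
    for (i in seq_len(nrow(sub))) {
      s <- sub$sex_type[i]
      ev <- align_to_model(sub$sequence[i], model, ref)
      tr <- translate_cds(sub$sequence[i], model, ref)
      per_sex[[s]] <- list(events = ev, truncated = tr$truncated)
      aa[[s]] <- tr$aa
    }
    present <- c(F = "F" %in% names(per_sex), M = "M" %in% names(per_sex),
                 H = "H" %in% names(per_sex))
    sexes <- names(per_sex)
    aa_id <- logical(0)
    if (length(sexes) >= 2L) {
      prs <- utils::combn(sort(sexes), 2L)
      aa_id <- apply(prs, 2L, function(p) identical(aa[[p[1]]], aa[[p[2]]]))
      names(aa_id) <- apply(prs, 2L, paste, collapse = ":")
      # canonical pair order F:M, F:H, M:H
      names(aa_id) <- vapply(strsplit(names(aa_id), ":"), function(p) {
        p <- p[order(match(p, c("F", "M", "H")))]
        paste(p, collapse = ":")
      }, "")
    }
    category <- if (length(per_sex) >= 2L) classify_as_category(per_sex)
                else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, n_sexes = length(per_sex), category = category,
      sex_group_type = classify_sex_group_type(present, aa_id),
      events = jsonlite::toJSON(lapply(per_sex, function(x)
        x$events[, c("type", "index", "pos", "len")]), dataframe = "rows",
        na = "null"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
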