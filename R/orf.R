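# Protein-guided, frameshift-aware ORF inference for accepted assignments,
# replacing an external protein-to-DNA aligner with a built-in dynamic
# program; an adapter for external aligner output is provided.

#' Pick the reference protein guiding ORF inference
#'
#' Returns the group member most similar to the assigned region: the
#' highest Smith-Waterman score of the assignment's amino-acid subsequence
#' against each member (ties: protein id).
#'
#' @param assignment one row of the assignments data.frame
#' @param ortholog_set an `ortholog_set`
#' @param config a [run_config()]
#' @return list `protein_id`, `sequence`, `score`
#' @export
pick_reference <- function(assignment, ortholog_set, config = run_config()) {
  cfg <- as_run_config(config)
  g <- ortholog_set$groups[[assignment$og_id]]
  stopifnot(!is.null(g), nrow(g$members) >= 1L)
  ids <- sort(g$members$protein_id)
  seqs <- setNames(ortholog_set$proteins$sequence,
                   ortholog_set$proteins$protein_id)[ids]
  scores <- vapply(seqs, function(s)
    smith_waterman(assignment$aa_seq, s, gap_open = cfg$gap_open,
                   gap_extend = cfg$gap_extend)$score, 0)
  best <- ids[which.max(scores)] # which.max takes the first on ties
  list(protein_id = best, sequence = unname(seqs[[best]]),
       score = unname(scores[[best]]))
}

#' Frameshift-aware protein-to-DNA alignment
#'
#' Local dynamic program aligning a guide protein to a nucleotide sequence
#' with codon matches (BLOSUM62 on the translated codon), affine codon
#' gaps, and frameshift transitions that excise one or two nucleotides (or
#' record one or two missing ones) at a fixed penalty. Emitted stop codons
#' score at the stop penalty. The decoded path yields the ORF skeleton:
#' emitted codon positions, frameshift events, and the exactly
#' corresponding amino-acid and nucleotide sequences.
#'
#' @param protein guide amino-acid string
#' @param dna nucleotide string (already strand-resolved)
#' @param config a [run_config()]
#' @return an `orf_skeleton`: list with `found`, `score`, `codon_starts`
#'   (0-based on `dna`), `frameshifts` (data.frame `pos`, `size`),
#'   `aa`, `nt`, `prot_start`, `prot_end`, `dna_start`, `dna_end`
#' @export
frameshift_align <- function(protein, dna, config = run_config()) {
  cfg <- as_run_config(config)
  stopifnot(nchar(protein) > 0L, nchar(dna) > 0L)
  mat <- blosum62()
  ct <- codon_table5()
  codon_aa <- aa_to_mat_idx(ct)
  codon_aa[ct == "*"] <- match("*", rownames(mat)) - 1L
  r <- frameshift_align_cpp(aa_to_mat_idx(split_chars(protein)),
                            nt_to_int5(dna), mat, codon_aa,
                            match("*", rownames(mat)) - 1L,
                            cfg$gap_open, cfg$gap_extend,
                            cfg$frameshift_penalty, cfg$stop_penalty)
  if (!r$found) {
    return(structure(list(found = FALSE, score = 0), class = "orf_skeleton"))
  }
  nt <- paste(substring(dna, r$codon_starts + 1L, r$codon_starts + 3L),
              collapse = "")
  structure(list(
    found = TRUE, score = r$score, codon_starts = r$codon_starts,
    frameshifts = data.frame(pos = r$fs_pos, size = r$fs_size),
    aa = translate_nt(nt), nt = nt,
    prot_start = r$prot_start, prot_end = r$prot_end,
    dna_start = r$dna_start, dna_end = r$dna_end), class = "orf_skeleton")
}

#' Adapter for external protein-to-DNA aligner output
#'
#' Builds an `orf_skeleton` from codon segments reported by an external
#' aligner, so external backends can replace [frameshift_align()].
#'
#' @param dna strand-resolved nucleotide string
#' @param segments data.frame with 0-based half-open `start`, `end` codon
#'   segments on `dna` (`end - start` divisible by 3)
#' @param frameshifts optional data.frame `pos`, `size`
#' @return an `orf_skeleton`
#' @export
orf_skeleton_from_segments <- function(dna, segments, frameshifts = NULL) {
  stopifnot(all((segments$end - segments$start) %% 3L == 0L),
            all(segments$start >= 0L), all(segments$end <= nchar(dna)))
  segments <- segments[order(segments$start), , drop = FALSE]
  codon_starts <- unlist(lapply(seq_len(nrow(segments)), function(i)
    seq(segments$start[i], segments$end[i] - 3L, by = 3L)))
  nt <- paste(substring(dna, codon_starts + 1L, codon_starts + 3L),
              collapse = "")
  structure(list(
    found = TRUE, score = NA_real_, codon_starts = codon_starts,
    frameshifts = if (is.null(frameshifts))
      data.frame(pos = integer(), size = integer()) else frameshifts,
    aa = translate_nt(nt), nt = nt,
    prot_start = NA_integer_, prot_end = NA_integer_,
    dna_start = codon_starts[1L],
    dna_end = codon_starts[length(codon_starts)] + 3L),
    class = "orf_skeleton")
}

#' Extend an ORF skeleton under the coverage constraint
#'
#' Extends the ORF outward codon by codon in the established frame until a
#' stop codon or the transcript end, then enforces that the
#' best-reciprocal-hit region covers at least `min_orf_coverage` of the
#' final ORF length (in amino acids) by trimming the extension from both
#' ends alternately -- never inside the hit region. An in-frame stop inside
#' an extension terminates the extension there.
#'
#' @param skeleton an `orf_skeleton` from [frameshift_align()]
#' @param brh_region length-2 vector: 0-based half-open nucleotide interval
#'   of the best-reciprocal-hit region on `dna`
#' @param dna the same strand-resolved nucleotide string
#' @param config a [run_config()]
#' @return an `orf_result`: skeleton fields plus `coverage` and `segments`
#'   (data.frame `start`, `end`, `frame`, 0-based half-open on `dna`)
#' @export
extend_orf <- function(skeleton, brh_region, dna, config = run_config()) {
  cfg <- as_run_config(config)
  stopifnot(isTRUE(skeleton$found), length(brh_region) == 2L)
  L <- nchar(dna)
  starts <- skeleton$codon_starts
  is_stop <- function(s) {
    codon_table5()[sum(c(25L, 5L, 1L) *
                         nt_to_int5(substr(dna, s + 1L, s + 3L))) + 1L] == "*"
  }
  left <- integer(); right <- integer()
  s <- starts[1L] - 3L
  while (s >= 0L && !is_stop(s)) { left <- c(s, left); s <- s - 3L }
  s <- starts[length(starts)] + 3L
  while (s + 3L <= L && !is_stop(s)) { right <- c(right, s); s <- s + 3L }
  all_starts <- c(left, starts, right)
  brh_aa_len <- (brh_region[2L] - brh_region[1L]) / 3
  in_brh <- (all_starts + 3L) > brh_region[1L] & all_starts < brh_region[2L]
  repeat {
    cov <- min(1, brh_aa_len / length(all_starts))
    if (cov >= cfg$min_orf_coverage) break
    # trim outside the hit region, symmetrically (longer outside run first)
    nl <- match(TRUE, in_brh) - 1L
    nr <- length(in_brh) - max(which(in_brh))
    if (is.na(nl) || (nl <= 0L && nr <= 0L)) break
    if (nl >= nr) {
      all_starts <- all_starts[-1L]; in_brh <- in_brh[-1L]
    } else {
      all_starts <- all_starts[-length(all_starts)]
      in_brh <- in_brh[-length(in_brh)]
    }
  }
  nt <- paste(substring(dna, all_starts + 1L, all_starts + 3L),
              collapse = "")
  brk <- which(diff(all_starts) != 3L)
  seg_start <- all_starts[c(1L, brk + 1L)]
  seg_last <- all_starts[c(brk, length(all_starts))]
  segments <- data.frame(start = seg_start, end = seg_last + 3L,
                         frame = seg_start %% 3L + 1L)
  out <- skeleton
  out$codon_starts <- all_starts
  out$nt <- nt
  out$aa <- translate_nt(nt)
  out$coverage <- min(1, brh_aa_len / length(all_starts))
  out$segments <- segments
  out$dna_start <- all_starts[1L]
  out$dna_end <- all_starts[length(all_starts)] + 3L
  class(out) <- c("orf_result", "orf_skeleton")
  out
}

#' Infer ORFs for all assignments
#'
#' For each assignment: picks the guiding reference ([pick_reference()]),
#' strand-resolves the transcript, runs [frameshift_align()] and
#' [extend_orf()]. Assignments for which no positive-scoring ORF exists
#' are kept but flagged (`orf` is `NULL`).
#'
#' @param assignments assignments data.frame from [assign_all()]
#' @param ortholog_set an `ortholog_set`
#' @param transcripts data.frame `transcript_id`, `sequence`
#' @param config a [run_config()]
#' @return named list (by assignment row) of `orf_result` or `NULL`
#' @export
refine_orfs <- function(assignments, ortholog_set, transcripts,
                        config = run_config()) {
  cfg <- as_run_config(config)
  seq_of <- setNames(transcripts$sequence, transcripts$transcript_id)
  out <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, , drop = FALSE]
    ref <- pick_reference(a, ortholog_set, cfg)
    dna <- seq_of[[a$transcript_id]]
    if (a$strand == "-") dna <- revcomp(dna)
    sk <- frameshift_align(ref$sequence, dna, cfg)
    if (!sk$found) {
      out[[i]] <- NULL
      next
    }
    L <- nchar(dna)
    brh <- if (a$strand == "+") c(a$nt_start, a$nt_end)
           else c(L - a$nt_end, L - a$nt_start)
    orf <- extend_orf(sk, brh, dna, cfg)
    orf$reference_protein <- ref$protein_id
    out[[i]] <- orf
  }
  names(out) <- rownames(assignments)
  out
}
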