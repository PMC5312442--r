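# The "analyzer" stage: six-frame translation, forward profile search over
# the transcript library, and reverse Smith-Waterman search of matched
# regions against the full reference protein database.

#' Six-frame translation of a transcript
#'
#' Frames `+1..+3` read the forward strand at offsets 0..2, `-1..-3` the
#' reverse complement likewise. Trailing 1-2 nt are dropped; stop codons
#' render as `*`, `N`-containing codons as `X`.
#'
#' @param nt_sequence nucleotide string over `ACGTN`
#' @return named list of six frames, each `list(frame, strand, offset, aa)`
#' @export
six_frame_translate <- function(nt_sequence) {
  L <- nchar(nt_sequence)
  if (L < 3L) warning("sequence shorter than one codon; frames are empty")
  rc <- revcomp(nt_sequence)
  out <- list()
  for (o in 0:2) {
    out[[paste0("+", o + 1L)]] <- list(
      frame = paste0("+", o + 1L), strand = "+", offset = o,
      aa = if (L - o >= 3L) translate_nt(substr(nt_sequence, o + 1L, L)) else "")
    out[[paste0("-", o + 1L)]] <- list(
      frame = paste0("-", o + 1L), strand = "-", offset = o,
      aa = if (L - o >= 3L) translate_nt(substr(rc, o + 1L, L)) else "")
  }
  out[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

# map a half-open aa interval on a translated frame to forward-strand
# nucleotide coordinates (0-based half-open)
aa_to_nt_coords <- function(frame, aa_start, aa_end, nt_len) {
  o <- as.integer(substr(frame, 2L, 2L)) - 1L
  if (substr(frame, 1L, 1L) == "+") {
    c(nt_start = o + 3L * aa_start, nt_end = o + 3L * aa_end)
  } else {
    c(nt_start = nt_len - o - 3L * aa_end, nt_end = nt_len - o - 3L * aa_start)
  }
}

# recursively collect non-overlapping local profile hits within one frame
frame_hits <- function(model, aa, base, cfg, db_residues, depth = 0L) {
  if (nchar(aa) < cfg$min_hit_aa || depth >= cfg$max_hits_per_frame)
    return(NULL)
  r <- score_sequence(model, aa, db_residues, stop_lod = cfg$stop_lod)
  if (r$bits < cfg$fwd_min_bits || r$evalue > cfg$fwd_max_evalue ||
      r$seq_end <= r$seq_start)
    return(NULL)
  hit <- data.frame(bit_score = r$bits, evalue = r$evalue,
                    aa_start = base + r$seq_start, aa_end = base + r$seq_end,
                    hmm_start = r$hmm_start, hmm_end = r$hmm_end)
  rbind(hit,
        frame_hits(model, substr(aa, 1L, r$seq_start), base, cfg,
                   db_residues, depth + 1L),
        frame_hits(model, substr(aa, r$seq_end + 1L, nchar(aa)),
                   base + r$seq_end, cfg, db_residues, depth + 1L))
}

#' Forward search: profile models against a transcript library
#'
#' Scores every (group, frame) pair, keeping hits that satisfy the bit and
#' E-value thresholds. Several non-overlapping local hits per (group,
#' transcript) are permitted. The E-value database size is the total
#' residue count over all six-frame translations of the library.
#'
#' @param profiles named list of `profile_model` (names = og ids)
#' @param transcripts data.frame with `transcript_id`, `sequence`
#' @param config a [run_config()]
#' @return data.frame of forward hits with translated-frame and
#'   forward-strand nucleotide coordinates (0-based half-open) and the
#'   matched aa subsequence (the reverse-search query)
#' @export
forward_search <- function(profiles, transcripts, config = run_config()) {
  cfg <- as_run_config(config)
  frames <- lapply(seq_len(nrow(transcripts)), function(i)
    six_frame_translate(transcripts$sequence[i]))
  db_residues <- sum(vapply(frames, function(fr)
    sum(vapply(fr, function(f) nchar(f$aa), 0L)), 0))
  rows <- list()
  for (og in names(profiles)) {
    model <- profiles[[og]]
    for (i in seq_len(nrow(transcripts))) {
      nt_len <- nchar(transcripts$sequence[i])
      for (f in frames[[i]]) {
        if (!nzchar(f$aa)) next
        h <- frame_hits(model, f$aa, 0L, cfg, db_residues)
        if (is.null(h) || !nrow(h)) next
        cds <- t(vapply(seq_len(nrow(h)), function(k)
          aa_to_nt_coords(f$frame, h$aa_start[k], h$aa_end[k], nt_len),
          c(nt_start = 0L, nt_end = 0L)))
        h$og_id <- og
        h$transcript_id <- transcripts$transcript_id[i]
        h$frame <- f$frame
        h$strand <- f$strand
        h$nt_start <- cds[, "nt_start"]
        h$nt_end <- cds[, "nt_end"]
        h$aa_seq <- substr(rep(f$aa, nrow(h)), h$aa_start + 1L, h$aa_end)
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (!length(rows)) return(empty_forward_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$og_id, out$transcript_id, out$frame, out$aa_start), ,
             drop = FALSE]
  out$hit_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("hit_id", "og_id", "transcript_id", "frame", "strand",
          "bit_score", "evalue", "aa_start", "aa_end", "hmm_start",
          "hmm_end", "nt_start", "nt_end", "aa_seq")]
}

empty_forward_hits <- function() {
  data.frame(hit_id = integer(), og_id = character(),
             transcript_id = character(), frame = character(),
             strand = character(), bit_score = numeric(), evalue = numeric(),
             aa_start = integer(), aa_end = integer(), hmm_start = integer(),
             hmm_end = integer(), nt_start = integer(), nt_end = integer(),
             aa_seq = character(), stringsAsFactors = FALSE)
}

empty_reverse_hits <- function() {
  data.frame(target_protein_id = character(),
             raw_score = numeric(), bit_score = numeric(), evalue = numeric(),
             aln_len = integer(), rank = integer(), stringsAsFactors = FALSE)
}

#' Karlin-Altschul bit score
#'
#' Converts a raw local-alignment score to bits, `(lambda*S - ln K)/ln 2`.
#' Defaults are the conventional gapped BLOSUM62 parameters.
#' @param raw raw Smith-Waterman score
#' @param lambda,K Karlin-Altschul parameters
#' @return bit score
#' @export
ka_bits <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' Optimal local alignment of two amino-acid sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (tie order:
#' diagonal, then gap in `b`, then gap in `a`). Unknown residues score
#' through the matrix's `X` column.
#'
#' @param a,b amino-acid strings
#' @param matrix substitution matrix (default [blosum62()])
#' @param gap_open,gap_extend affine gap costs
#' @return list with `score` and 0-based half-open envelopes `a_start`,
#'   `a_end`, `b_start`, `b_end`
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  sw_align_cpp(aa_to_mat_idx(split_chars(a)), aa_to_mat_idx(split_chars(b)),
               matrix, gap_open, gap_extend)
}

# seed-word candidate screen for heuristic mode: keep targets with either
# two query words on one diagonal within the window (two-hit rule) or, for
# short queries, any single word
heuristic_candidates <- function(query, targets, cfg) {
  w <- cfg$seed_len
  nq <- nchar(query)
  if (nq < w) return(rep(FALSE, length(targets)))
  qpos <- seq_len(nq - w + 1L)
  qwords <- substring(query, qpos, qpos + w - 1L)
  single_ok <- nq < (2L * w + 2L) || !cfg$two_hit
  vapply(targets, function(t) {
    nt <- nchar(t)
    if (nt < w) return(FALSE)
    tpos <- seq_len(nt - w + 1L)
    twords <- substring(t, tpos, tpos + w - 1L)
    hits <- which(twords %in% qwords)
    if (!length(hits)) return(FALSE)
    if (single_ok) return(TRUE)
    # diagonals carrying >= 2 non-overlapping word hits within the window
    dq <- unlist(lapply(hits, function(tp) {
      qp <- qpos[qwords == twords[tp]]
      (tp - qp) * 10000L + qp
    }))
    diag <- dq %/% 10000L
    qp <- dq %% 10000L
    for (d in unique(diag)) {
      p <- sort(unique(qp[diag == d]))
      if (length(p) < 2L) next
      for (i in seq_len(length(p) - 1L)) {
        gap <- p[(i + 1L):length(p)] - p[i]
        if (any(gap >= w & gap <= cfg$two_hit_window)) return(TRUE)
      }
    }
    FALSE
  }, FALSE)
}

#' Reverse search of a matched region against the reference protein database
#'
#' The query is exactly the amino-acid subsequence matched by the forward
#' profile search, never more. In `"exact"` mode every database protein is
#' scanned with full Smith-Waterman (SWIPE-like); in `"heuristic"` mode only
#' proteins passing a seed-word screen are aligned (BLAST-like). Raw scores
#' are converted to bits with [ka_bits()]; hits below `rev_min_bits` are
#' dropped, the rest ranked by descending bits (ties: longer alignment,
#' then protein id).
#'
#' @param query_aa amino-acid query (forward-hit subsequence)
#' @param proteins data.frame with `protein_id`, `sequence` (the full
#'   reference gene set, including proteins in no group)
#' @param config a [run_config()]
#' @param db_residues database size for E-values (default: total residues
#'   in `proteins`)
#' @return data.frame of reverse hits with `rank` (1 = best)
#' @export
reverse_search <- function(query_aa, proteins, config = run_config(),
                           db_residues = sum(nchar(proteins$sequence))) {
  cfg <- as_run_config(config)
  if (!nzchar(query_aa)) stop("empty reverse-search query")
  idx <- if (cfg$search_mode == "heuristic") {
    which(heuristic_candidates(query_aa, proteins$sequence, cfg))
  } else seq_len(nrow(proteins))
  if (!length(idx)) return(empty_reverse_hits())
  q <- aa_to_mat_idx(split_chars(query_aa))
  mat <- blosum62()
  res <- lapply(idx, function(i) {
    al <- sw_align_cpp(q, aa_to_mat_idx(split_chars(proteins$sequence[i])),
                       mat, cfg$gap_open, cfg$gap_extend)
    data.frame(target_protein_id = proteins$protein_id[i],
               raw_score = al$score,
               bit_score = ka_bits(al$score, cfg$lambda, cfg$K),
               aln_len = al$a_end - al$a_start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$evalue <- db_residues * 2^(-out$bit_score)
  out <- out[out$raw_score > 0 & out$bit_score >= cfg$rev_min_bits, ,
             drop = FALSE]
  if (!nrow(out)) return(empty_reverse_hits())
  out <- out[order(-out$bit_score, -out$aln_len, out$target_protein_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("target_protein_id", "raw_score", "bit_score", "evalue",
          "aln_len", "rank")]
}
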