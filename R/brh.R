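# The algorithmic core: global collation of forward hits by descending bit
# score with subordinated reverse results, best-reciprocal-hit evaluation,
# and single-pass greedy assignment under a region ledger that guarantees
# non-redundancy.

#' Collate forward and reverse hits into ordered candidate pairs
#'
#' Candidates are ordered by descending forward bit score; ties are broken
#' by lower E-value, then longer forward envelope, then (transcript_id,
#' og_id) lexicographically, so the ordering is total and deterministic and
#' independent of input row order. Each candidate carries its reverse hits
#' sorted by descending bit score (ties: longer alignment, then protein
#' id). Forward hits without reverse hits are retained; they simply fail
#' the reciprocal criterion later.
#'
#' @param forward_hits data.frame from [forward_search()]
#' @param reverse_hits data.frame of reverse hits carrying a `hit_id`
#'   column referencing the forward hit
#' @return list of candidate pairs, each `list(fwd, rev)`
#' @export
collate <- function(forward_hits, reverse_hits) {
  if (!nrow(forward_hits)) return(list())
  env_len <- forward_hits$aa_end - forward_hits$aa_start
  ord <- order(-forward_hits$bit_score, forward_hits$evalue, -env_len,
               forward_hits$transcript_id, forward_hits$og_id,
               forward_hits$aa_start)
  fwd <- forward_hits[ord, , drop = FALSE]
  rev_by_hit <- if (nrow(reverse_hits)) {
    split(reverse_hits, reverse_hits$hit_id)
  } else list()
  lapply(seq_len(nrow(fwd)), function(i) {
    rv <- rev_by_hit[[as.character(fwd$hit_id[i])]]
    if (is.null(rv)) rv <- empty_reverse_hits()
    else {
      rv <- rv[order(-rv$bit_score, -rv$aln_len, rv$target_protein_id), ,
               drop = FALSE]
      rv$rank <- seq_len(nrow(rv))
      rownames(rv) <- NULL
    }
    list(fwd = fwd[i, , drop = FALSE], rev = rv)
  })
}

#' Evaluate the best-reciprocal-hit criterion for one candidate
#'
#' Accepts when the rank-1 reverse hit belongs to the ortholog group that
#' the forward profile was built from. If several reverse hits tie at the
#' rank-1 bit score, one tied member suffices by default; under
#' `strict` all tied proteins must be members.
#'
#' @param pair a candidate pair from [collate()]
#' @param ortholog_set an `ortholog_set`
#' @param strict tie handling (see above)
#' @return list `accept` (logical) and `reason` (`NA` when accepted, else
#'   `"no_reverse_hit"` or `"best_hit_outside_og"`)
#' @export
evaluate_brh <- function(pair, ortholog_set, strict = FALSE) {
  rv <- pair$rev
  if (!nrow(rv)) return(list(accept = FALSE, reason = "no_reverse_hit"))
  top <- rv[rv$bit_score == rv$bit_score[1L], , drop = FALSE]
  member <- og_of(ortholog_set, top$target_protein_id) == pair$fwd$og_id
  member[is.na(member)] <- FALSE
  ok <- if (strict) all(member) else any(member)
  if (ok) list(accept = TRUE, reason = NA_character_)
  else list(accept = FALSE, reason = "best_hit_outside_og")
}

# interval overlap in nt between [s,e) and a 2-column matrix of claims
claimed_overlap <- function(claims, s, e) {
  if (is.null(claims) || !nrow(claims)) return(0L)
  max(pmax(0L, pmin(claims[, 2L], e) - pmax(claims[, 1L], s)))
}

#' Greedy global assignment under the region ledger
#'
#' Processes collated candidates in a single pass of descending forward bit
#' score. A candidate failing the reciprocal criterion is rejected with its
#' reason; a candidate whose transcript region overlaps an already claimed
#' region by more than `max_overlap` amino acids (default 0: any overlap)
#' is rejected as `region_already_claimed`. Accepted candidates claim their
#' nucleotide interval (or, with the `"transcript"` ledger, the whole
#' transcript). Several transcripts may be assigned to one group
#' (co-orthologs, inparalogs, alternative transcripts); no transcript
#' position is ever assigned twice.
#'
#' @param pairs output of [collate()]
#' @param ortholog_set an `ortholog_set`
#' @param config a [run_config()]
#' @return list with `assignments` and `rejections` data.frames
#' @export
assign_all <- function(pairs, ortholog_set, config = run_config()) {
  cfg <- as_run_config(config)
  ledger <- new.env(parent = emptyenv())
  max_ov_nt <- 3L * cfg$max_overlap
  acc <- list(); rej <- list()
  for (pair in pairs) {
    fwd <- pair$fwd
    ev <- evaluate_brh(pair, ortholog_set, strict = cfg$strict_brh)
    reason <- ev$reason
    if (ev$accept) {
      claims <- ledger[[fwd$transcript_id]]
      blocked <- if (cfg$ledger == "transcript") {
        !is.null(claims)
      } else {
        claimed_overlap(claims, fwd$nt_start, fwd$nt_end) > max_ov_nt
      }
      if (blocked) {
        reason <- "region_already_claimed"
      } else {
        ledger[[fwd$transcript_id]] <-
          rbind(claims, c(fwd$nt_start, fwd$nt_end))
        acc[[length(acc) + 1L]] <- data.frame(
          og_id = fwd$og_id, transcript_id = fwd$transcript_id,
          strand = fwd$strand, frame = fwd$frame,
          nt_start = fwd$nt_start, nt_end = fwd$nt_end,
          aa_start = fwd$aa_start, aa_end = fwd$aa_end,
          hmm_start = fwd$hmm_start, hmm_end = fwd$hmm_end,
          aa_seq = fwd$aa_seq, fwd_bits = fwd$bit_score,
          fwd_evalue = fwd$evalue,
          rev_protein_id = pair$rev$target_protein_id[1L],
          rev_bits = pair$rev$bit_score[1L],
          hit_id = fwd$hit_id, stringsAsFactors = FALSE)
        next
      }
    }
    rej[[length(rej) + 1L]] <- data.frame(
      og_id = fwd$og_id, transcript_id = fwd$transcript_id,
      nt_start = fwd$nt_start, nt_end = fwd$nt_end,
      fwd_bits = fwd$bit_score, reason = reason, hit_id = fwd$hit_id,
      stringsAsFactors = FALSE)
  }
  list(assignments = if (length(acc)) do.call(rbind, acc) else
         empty_assignments(),
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(og_id = character(), transcript_id = character(),
                    nt_start = integer(), nt_end = integer(),
                    fwd_bits = numeric(), reason = character(),
                    hit_id = integer(), stringsAsFactors = FALSE))
}

empty_assignments <- function() {
  data.frame(og_id = character(), transcript_id = character(),
             strand = character(), frame = character(),
             nt_start = integer(), nt_end = integer(),
             aa_start = integer(), aa_end = integer(),
             hmm_start = integer(), hmm_end = integer(),
             aa_seq = character(), fwd_bits = numeric(),
             fwd_evalue = numeric(), rev_protein_id = character(),
             rev_bits = numeric(), hit_id = integer(),
             stringsAsFactors = FALSE)
}

#' Re-evaluate stored search results under new thresholds
#'
#' Filters the persisted forward and reverse hits by the thresholds in
#' `config` (forward bit score and E-value, reverse bit score), re-ranks
#' the reverse hits, and repeats collation and greedy assignment. No search
#' is executed, so parameters can be explored at a fraction of the original
#' run time.
#'
#' @param store a run store directory (see [store_create()])
#' @param config a [run_config()]
#' @return list with `assignments` and `rejections`
#' @export
brh_reevaluate <- function(store, config = run_config()) {
  cfg <- as_run_config(config)
  hits <- store_read_hits(store)
  set <- store_read_ortholog_set(store)
  fwd <- hits$forward
  fwd <- fwd[fwd$bit_score >= cfg$fwd_min_bits &
               fwd$evalue <= cfg$fwd_max_evalue, , drop = FALSE]
  rev <- hits$reverse
  rev <- rev[rev$bit_score >= cfg$rev_min_bits, , drop = FALSE]
  assign_all(collate(fwd, rev), set, cfg)
}
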