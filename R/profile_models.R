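# Per-group multiple sequence alignment and profile-HMM construction, plus
# the local Viterbi scorer used by the forward search.

#' Align the members of one ortholog group
#'
#' Deterministic progressive alignment by the center-star method: the
#' sequence with the highest summed pairwise global-alignment score (i.e.
#' minimal summed distance) is the center, all others are merged into the
#' growing alignment through their pairwise BLOSUM62 global alignment with
#' the center. A pre-computed alignment from an external aligner can be
#' supplied via `precomputed` (named gapped strings of equal length).
#'
#' @param group_sequences named character vector, protein_id -> aa sequence
#' @param gap_open,gap_extend affine gap costs
#' @param precomputed optional named character vector of gapped rows
#' @return an `og_alignment`: list with `rows` (named gapped strings) and
#'   `ncols`
#' @export
align_og <- function(group_sequences, gap_open = 11, gap_extend = 1,
                     precomputed = NULL) {
  if (!is.null(precomputed)) {
    stopifnot(length(unique(nchar(precomputed))) == 1L)
    degap <- gsub("-", "", precomputed, fixed = TRUE)
    stopifnot(all(sort(names(precomputed)) == sort(names(group_sequences))),
              all(degap[names(group_sequences)] == group_sequences))
    return(structure(list(rows = precomputed,
                          ncols = nchar(precomputed[[1L]])),
                     class = "og_alignment"))
  }
  stopifnot(length(group_sequences) >= 1L, !is.null(names(group_sequences)))
  seqs <- group_sequences[order(names(group_sequences))]
  n <- length(seqs)
  if (n == 1L) {
    return(structure(list(rows = seqs, ncols = nchar(seqs[[1L]])),
                     class = "og_alignment"))
  }
  mat <- blosum62()
  ints <- lapply(seqs, function(s) aa_to_mat_idx(split_chars(s)))
  score_sum <- numeric(n)
  aligns <- vector("list", n)
  for (i in seq_len(n)) aligns[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      al <- nw_align_cpp(ints[[i]], ints[[j]], mat, gap_open, gap_extend)
      score_sum[i] <- score_sum[i] + al$score
      score_sum[j] <- score_sum[j] + al$score
    }
  }
  center <- which.max(score_sum) # ties: first in id order
  others <- setdiff(seq_len(n), center)
  # msa state: matrix of single chars, rows in input order added so far;
  # center_res[k] = index of center residue in column k (NA = gap column)
  c_chars <- split_chars(seqs[[center]])
  msa <- matrix(c_chars, nrow = 1L)
  rown <- names(seqs)[center]
  center_res <- seq_along(c_chars)
  for (o in others) {
    al <- nw_align_cpp(ints[[center]], ints[[o]], mat, gap_open, gap_extend)
    o_chars <- split_chars(seqs[[o]])
    new_cols <- list(); i <- 1L; j <- 1L
    nmsa <- ncol(msa); nal <- length(al$a_idx)
    new_center_res <- integer(0)
    while (i <= nmsa || j <= nal) {
      msa_has_center <- i <= nmsa && !is.na(center_res[i])
      al_has_center <- j <= nal && !is.na(al$a_idx[j])
      if (i <= nmsa && !msa_has_center) {
        # gap column from an earlier merge: new row gets a gap
        new_cols[[length(new_cols) + 1L]] <- c(msa[, i], "-")
        new_center_res <- c(new_center_res, NA_integer_)
        i <- i + 1L
      } else if (j <= nal && !al_has_center) {
        # insertion in the new sequence: all earlier rows get a gap
        ch <- if (is.na(al$b_idx[j])) "-" else o_chars[al$b_idx[j]]
        new_cols[[length(new_cols) + 1L]] <- c(rep("-", nrow(msa)), ch)
        new_center_res <- c(new_center_res, NA_integer_)
        j <- j + 1L
      } else {
        # both at the same center residue
        ch <- if (is.na(al$b_idx[j])) "-" else o_chars[al$b_idx[j]]
        new_cols[[length(new_cols) + 1L]] <- c(msa[, i], ch)
        new_center_res <- c(new_center_res, center_res[i])
        i <- i + 1L; j <- j + 1L
      }
    }
    msa <- do.call(cbind, new_cols)
    center_res <- new_center_res
    rown <- c(rown, names(seqs)[o])
  }
  rows <- apply(msa, 1L, paste, collapse = "")
  names(rows) <- rown
  rows <- rows[order(names(rows))]
  structure(list(rows = rows, ncols = ncol(msa)), class = "og_alignment")
}

#' Build a profile HMM from an ortholog-group alignment
#'
#' Columns whose residue occupancy is at least `match_occupancy` become
#' match states. Match emissions are Laplace-smoothed residue frequencies,
#' `(counts + w * background) / (n + w)`; transition probabilities among
#' match/insert/delete states are estimated from the per-row state paths
#' with the same pseudocount scheme. Insert states emit at background.
#'
#' @param alignment an `og_alignment`
#' @param pseudocount pseudocount weight `w`
#' @param match_occupancy match-column occupancy threshold
#' @param background residue background frequencies over [AA20] order
#'   (default uniform 1/20)
#' @param og_id group label carried on the model
#' @return a `profile_model`
#' @export
build_profile <- function(alignment, pseudocount = 1.0,
                          match_occupancy = 0.5,
                          background = rep(1 / 20, 20),
                          og_id = NA_character_) {
  stopifnot(inherits(alignment, "og_alignment"),
            length(background) == 20L,
            abs(sum(background) - 1) < 1e-9)
  chars <- do.call(rbind, lapply(alignment$rows, split_chars))
  nrow_ <- nrow(chars); ncol_ <- ncol(chars)
  occ <- colMeans(chars != "-")
  match_cols <- which(occ >= match_occupancy)
  M <- length(match_cols)
  if (M == 0L) stop("alignment has no match columns at occupancy >= ",
                    match_occupancy)
  w <- pseudocount
  emis <- matrix(0, nrow = M, ncol = 20L, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- chars[, match_cols[k]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    n <- sum(cnt)
    emis[k, ] <- (as.numeric(cnt) + w * background) / (n + w)
  }
  # state paths per row -> transition counts
  tc <- list(mm = numeric(max(M - 1L, 0L)), md = numeric(max(M - 1L, 0L)),
             mi = numeric(M), im = numeric(max(M - 1L, 0L)), ii = numeric(M),
             dm = numeric(max(M - 1L, 0L)), dd = numeric(max(M - 1L, 0L)))
  is_match_col <- logical(ncol_); is_match_col[match_cols] <- TRUE
  state_of_col <- integer(ncol_) # match index, or index of preceding match
  k <- 0L
  for (cc in seq_len(ncol_)) {
    if (is_match_col[cc]) k <- k + 1L
    state_of_col[cc] <- k
  }
  for (r in seq_len(nrow_)) {
    prev <- NULL # c(type, k): type 1 M, 2 I, 3 D
    for (cc in seq_len(ncol_)) {
      ch <- chars[r, cc]
      k <- state_of_col[cc]
      cur <- if (is_match_col[cc]) {
        c(if (ch == "-") 3L else 1L, k)
      } else if (ch != "-") c(2L, k) else NULL
      if (is.null(cur)) next
      if (!is.null(prev)) {
        pt <- prev[1L]; pk <- prev[2L]; ct <- cur[1L]
        if (pt == 1L && ct == 1L) tc$mm[pk] <- tc$mm[pk] + 1
        else if (pt == 1L && ct == 3L) tc$md[pk] <- tc$md[pk] + 1
        else if (pt == 1L && ct == 2L) tc$mi[pk] <- tc$mi[pk] + 1
        else if (pt == 2L && ct == 2L) tc$ii[pk] <- tc$ii[pk] + 1
        else if (pt == 2L && ct == 1L) tc$im[pk] <- tc$im[pk] + 1
        else if (pt == 2L && ct == 3L) tc$im[pk] <- tc$im[pk] + 1 # fold I->D
        else if (pt == 3L && ct == 1L) tc$dm[pk] <- tc$dm[pk] + 1
        else if (pt == 3L && ct == 3L) tc$dd[pk] <- tc$dd[pk] + 1
        else if (pt == 3L && ct == 2L) tc$dm[pk] <- tc$dm[pk] + 1 # fold D->I
      }
      prev <- cur
    }
  }
  norm3 <- function(a, b, c3, w) {
    tot <- a + b + c3 + w
    c((a + w / 3) / tot, (b + w / 3) / tot, (c3 + w / 3) / tot)
  }
  norm2 <- function(a, b, w) {
    tot <- a + b + w
    c((a + w / 2) / tot, (b + w / 2) / tot)
  }
  if (M > 1L) {
    tmm <- tmd <- tmi_ <- numeric(M - 1L)
    for (k in seq_len(M - 1L)) {
      v <- norm3(tc$mm[k], tc$md[k], tc$mi[k], w)
      tmm[k] <- v[1L]; tmd[k] <- v[2L]; tmi_[k] <- v[3L]
    }
    tmi <- c(tmi_, norm2(tc$mi[M], 0, w)[1L])
    tim <- tii <- numeric(M)
    for (k in seq_len(M - 1L)) {
      v <- norm2(tc$im[k], tc$ii[k], w)
      tim[k] <- v[1L]; tii[k] <- v[2L]
    }
    v <- norm2(0, tc$ii[M], w); tim[M] <- v[1L]; tii[M] <- v[2L]
    tdm <- tdd <- numeric(M - 1L)
    for (k in seq_len(M - 1L)) {
      v <- norm2(tc$dm[k], tc$dd[k], w)
      tdm[k] <- v[1L]; tdd[k] <- v[2L]
    }
  } else {
    tmm <- tmd <- tdm <- tdd <- numeric(0)
    v <- norm2(tc$mi[1L], 0, w); tmi <- v[1L]
    v <- norm2(0, tc$ii[1L], w); tim_last <- v[1L]; tii1 <- v[2L]
    tim <- numeric(0); tii <- tii1
  }
  structure(list(og_id = og_id, nmatch = M, match_cols = match_cols,
                 emis = emis, background = background,
                 trans = list(tmm = tmm, tmi = tmi, tmd = tmd,
                              tim = if (M > 1L) tim[seq_len(M - 1L)] else numeric(0),
                              tii = tii, tdm = tdm, tdd = tdd)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model '%s': %d match states\n", x$og_id, x$nmatch))
  invisible(x)
}

# encode an aa string for the viterbi kernel: 0..19 residues, 20 X, 21 stop
aa_to_int22 <- function(s) {
  ch <- split_chars(s)
  i <- match(ch, AA20)
  i[is.na(i) & ch == "*"] <- 22L
  i[is.na(i)] <- 21L
  i - 1L
}

#' Score a sequence against a profile model
#'
#' Local (Smith-Waterman style) Viterbi over the match/insert/delete
#' profile: the bit score is the log2 odds of the best local state path
#' relative to the background null, with free entry into and exit from any
#' match state. `X` scores as background (log-odds 0), `*` at `stop_lod`.
#' The E-value is the naive `db_residues * 2^-bits`; it is used for
#' reporting and thresholding only, never for candidate ordering.
#'
#' @param model a `profile_model`
#' @param aa_sequence amino-acid string
#' @param db_residues effective database size in residues (for the E-value;
#'   `NA` leaves the E-value `NA`)
#' @param stop_lod emission log-odds for stop symbols
#' @return list with `bits`, `evalue`, `seq_start`, `seq_end`, `hmm_start`,
#'   `hmm_end` (0-based half-open)
#' @export
score_sequence <- function(model, aa_sequence, db_residues = NA_real_,
                           stop_lod = -4) {
  stopifnot(inherits(model, "profile_model"), nchar(aa_sequence) >= 1L)
  lod <- cbind(log2(sweep(model$emis, 2L, model$background, "/")),
               0, stop_lod) # cols 21 = X, 22 = stop
  tr <- lapply(model$trans, log2)
  r <- profile_viterbi_cpp(aa_to_int22(aa_sequence), lod,
                           tr$tmm, tr$tmi, tr$tmd, tr$tim, tr$tii,
                           tr$tdm, tr$tdd)
  list(bits = r$bits,
       evalue = if (is.na(db_residues)) NA_real_ else
         db_residues * 2^(-r$bits),
       seq_start = r$seq_start, seq_end = r$seq_end,
       hmm_start = r$hmm_start, hmm_end = r$hmm_end)
}
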