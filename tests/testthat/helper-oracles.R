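# Independent reference implementations used as oracles. Each is written
# as a direct transcription of the scoring definition (plain-R dynamic
# programs or exhaustive path enumeration), deliberately separate from the
# package's compiled kernels.

# --- local affine-gap alignment score, plain R ------------------------------
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  mat <- blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F_[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      F_[i - 1, j] - gap_extend)
      H[i, j] <- max(0, E[i, j], F_[i, j],
                     H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- profile Viterbi by exhaustive local-path enumeration -------------------
# Enumerates every local state path (DFS over M/I/D moves) that starts and
# ends in a match state; feasible for tiny models and queries.
oracle_viterbi_enum <- function(model, aa, stop_lod = -4) {
  M <- model$nmatch
  x <- strsplit(aa, "")[[1]]
  L <- length(x)
  lod <- function(j, c) {
    if (c == "X") return(0)
    if (c == "*") return(stop_lod)
    log2(model$emis[j, c] / model$background[match(c, colnames(model$emis))])
  }
  tr <- lapply(model$trans, log2)
  best <- 0
  walk <- function(i, j, state, sc) {
    if (state == "M") best <<- max(best, sc)
    if (state == "M" && j < M) {
      if (i < L) walk(i + 1, j + 1, "M",
                      sc + tr$tmm[j] + lod(j + 1, x[i + 1]))
      if (i < L) walk(i + 1, j, "I", sc + tr$tmi[j])
      walk(i, j + 1, "D", sc + tr$tmd[j])
    } else if (state == "I" && j < M) {
      if (i < L) walk(i + 1, j, "I", sc + tr$tii[j])
      if (i < L) walk(i + 1, j + 1, "M",
                      sc + tr$tim[j] + lod(j + 1, x[i + 1]))
    } else if (state == "D" && j < M) {
      walk(i, j + 1, "D", sc + tr$tdd[j])
      if (i < L) walk(i + 1, j + 1, "M",
                      sc + tr$tdm[j] + lod(j + 1, x[i + 1]))
    }
  }
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      walk(i0, j0, "M", lod(j0, x[i0]))
    }
  }
  best
}

# --- frameshift protein-to-DNA score by exhaustive enumeration --------------
# Moves mirror the scoring definition: codon match (BLOSUM62 on the
# translated codon, stop penalty for stops), affine protein / codon gaps,
# and 1-2 nt frameshift excisions. Paths start and end on a match.
oracle_frameshift_enum <- function(protein, dna, gap_open = 11,
                                   gap_extend = 1, fs_pen = 15,
                                   stop_pen = 20) {
  mat <- blosum62()
  p <- strsplit(protein, "")[[1]]
  np <- length(p); nd <- nchar(dna)
  codon_aa <- function(j) { # aa of codon ending at dna position j (1-based)
    translate_nt(substr(dna, j - 2, j))
  }
  sub_score <- function(a, cd_aa) {
    if (cd_aa == "*") return(-stop_pen)
    mat[a, cd_aa]
  }
  best <- 0
  # state: H (after match/frameshift), P (protein gap), Q (codon gap)
  walk <- function(i, j, state, sc, ended_on_match) {
    if (state == "H" && ended_on_match) best <<- max(best, sc)
    # codon match
    if (i < np && j + 3 <= nd) {
      walk(i + 1, j + 3, "H", sc + sub_score(p[i + 1], codon_aa(j + 3)),
           TRUE)
    }
    # frameshift: excise 1-2 inserted nt (no emission)
    for (k in 1:2) if (j + k <= nd) {
      walk(i, j + k, "H", sc - fs_pen, FALSE)
    }
    # frameshift: protein residue with 1-2 surviving codon nt (no emission)
    for (k in 1:2) if (i < np && j + k <= nd) {
      walk(i + 1, j + k, "H", sc - fs_pen, FALSE)
    }
    # protein gap (affine)
    if (i < np) {
      cost <- if (state == "P") gap_extend else gap_open + gap_extend
      walk(i + 1, j, "P", sc - cost, FALSE)
    }
    # emitted unmatched codon (affine, stop-penalized)
    if (j + 3 <= nd) {
      cost <- if (state == "Q") gap_extend else gap_open + gap_extend
      extra <- if (codon_aa(j + 3) == "*") stop_pen else 0
      walk(i, j + 3, "Q", sc - cost - extra, FALSE)
    }
  }
  for (i0 in 0:(np - 1)) {
    for (j0 in 0:(nd - 3)) {
      walk(i0 + 1, j0 + 3, "H",
           sub_score(p[i0 + 1], codon_aa(j0 + 3)), TRUE)
    }
  }
  best
}

# --- independent greedy assignment ------------------------------------------
# Brute-force restatement of the global rule: order candidates by
# descending forward bits, accept reciprocal-positive ones whose region is
# still free, claim the region.
oracle_greedy <- function(cands, max_overlap_nt = 0) {
  cands <- cands[order(-cands$bits, cands$transcript_id, cands$og_id), ,
                 drop = FALSE]
  claimed <- list()
  out <- character()
  for (r in seq_len(nrow(cands))) {
    row <- cands[r, ]
    if (!row$brh_ok) next
    ivs <- claimed[[row$transcript_id]]
    free <- TRUE
    if (!is.null(ivs)) {
      for (k in seq_len(nrow(ivs))) {
        ov <- min(ivs[k, 2], row$nt_end) - max(ivs[k, 1], row$nt_start)
        if (ov > max_overlap_nt) { free <- FALSE; break }
      }
    }
    if (free) {
      claimed[[row$transcript_id]] <-
        rbind(ivs, c(row$nt_start, row$nt_end))
      out <- c(out, paste(row$transcript_id, row$og_id, row$nt_start,
                          sep = "/"))
    }
  }
  sort(out)
}

# random tiny profile model for oracle tests
random_model <- function(nmatch, nseq = 3, len = NULL) {
  if (is.null(len)) len <- nmatch
  seqs <- replicate(nseq, paste(sample(colnames(blosum62())[1:20],
                                       len, replace = TRUE),
                                collapse = ""))
  # restrict to the 20 canonical letters used by profiles
  seqs <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "A", seqs)
  names(seqs) <- paste0("s", seq_along(seqs))
  build_profile(align_og(seqs), og_id = "rand")
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- plain-R DP transcriptions (for sizes where enumeration is infeasible) --
oracle_viterbi_dp <- function(model, aa, stop_lod = -4) {
  M <- model$nmatch
  x <- strsplit(aa, "")[[1]]
  L <- length(x)
  lod <- function(j, c) {
    if (c == "X") return(0)
    if (c == "*") return(stop_lod)
    log2(model$emis[j, c] / model$background[match(c, colnames(model$emis))])
  }
  tr <- lapply(model$trans, log2)
  VM <- VI <- VD <- matrix(-Inf, L + 1, M + 1)
  best <- 0
  for (i in 1:L) {
    for (j in 1:M) {
      from <- 0
      if (j > 1) {
        from <- max(from, VM[i, j] + tr$tmm[j - 1],
                    VI[i, j] + tr$tim[j - 1],
                    VD[i, j] + tr$tdm[j - 1])
      }
      VM[i + 1, j + 1] <- lod(j, x[i]) + from
      VI[i + 1, j + 1] <- max(VM[i, j + 1] + tr$tmi[j],
                              VI[i, j + 1] + tr$tii[j])
      if (j > 1) {
        VD[i + 1, j + 1] <- max(VM[i + 1, j] + tr$tmd[j - 1],
                                VD[i + 1, j] + tr$tdd[j - 1])
      }
      best <- max(best, VM[i + 1, j + 1])
    }
  }
  best
}

oracle_frameshift_dp <- function(protein, dna, gap_open = 11,
                                 gap_extend = 1, fs_pen = 15,
                                 stop_pen = 20) {
  mat <- blosum62()
  p <- strsplit(protein, "")[[1]]
  np <- length(p); nd <- nchar(dna)
  caa <- vapply(3:nd, function(j) translate_nt(substr(dna, j - 2, j)), "")
  sub_score <- function(a, cd_aa) {
    if (cd_aa == "*") return(-stop_pen)
    mat[a, cd_aa]
  }
  H <- P <- Q <- matrix(-Inf, np + 1, nd + 1)
  ends_match <- matrix(FALSE, np + 1, nd + 1)
  best <- 0
  for (i in 0:np) {
    for (j in 0:nd) {
      if (i == 0 && j == 0) next
      h <- -Inf; em <- FALSE
      if (i >= 1 && j >= 3) {
        base <- max(0, H[i, j - 2], P[i, j - 2], Q[i, j - 2])
        v <- base + sub_score(p[i], caa[j - 2])
        if (v > h) { h <- v; em <- TRUE }
      }
      for (k in 1:2) if (j >= k) {
        v <- max(H[i + 1, j - k + 1], P[i + 1, j - k + 1],
                 Q[i + 1, j - k + 1]) - fs_pen
        if (v > h) { h <- v; em <- FALSE }
      }
      for (k in 1:2) if (i >= 1 && j >= k) {
        v <- max(H[i, j - k + 1], P[i, j - k + 1], Q[i, j - k + 1]) - fs_pen
        if (v > h) { h <- v; em <- FALSE }
      }
      H[i + 1, j + 1] <- h
      if (em && h > best) best <- h
      if (i >= 1) {
        P[i + 1, j + 1] <- max(max(H[i, j + 1], Q[i, j + 1]) -
                                 gap_open - gap_extend,
                               P[i, j + 1] - gap_extend)
      }
      if (j >= 3) {
        extra <- if (caa[j - 2] == "*") stop_pen else 0
        Q[i + 1, j + 1] <- max(max(H[i + 1, j - 2], P[i + 1, j - 2]) -
                                 gap_open - gap_extend,
                               Q[i + 1, j - 2] - gap_extend) - extra
      }
    }
  }
  best
}
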