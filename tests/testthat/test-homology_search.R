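test_that("six-frame translation follows the genetic code and frame offsets", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["+1"]]$aa, "MK")
  expect_equal(fr[["+2"]]$aa, "*") # offset 1 reads TGA, trailing AA dropped
  fr2 <- six_frame_translate("TTTAGA")
  expect_equal(fr2[["+2"]]$aa, "L")         # codon TTA
  fr3 <- six_frame_translate("ATG")
  expect_equal(fr3[["-1"]]$aa, "H")         # revcomp CAT
  # N-containing codons become X, stops become *
  fr4 <- six_frame_translate("ATGNNNTAA")
  expect_equal(fr4[["+1"]]$aa, "MX*")
  expect_warning(six_frame_translate("AT"), "shorter")
})

test_that("Smith-Waterman matches printed examples and the plain-R oracle", {
  expect_equal(smith_waterman("AAA", "AAA")$score, 12)
  expect_equal(smith_waterman("AAAA", "CCCC")$score, 0)
  set.seed(21)
  for (rep in 1:60) {
    a <- random_aa(sample(3:10, 1))
    b <- random_aa(sample(3:10, 1))
    expect_equal(smith_waterman(a, b)$score, oracle_sw_score(a, b),
                 info = paste(a, b))
  }
  # the classic textbook pair against the oracle too
  expect_equal(smith_waterman("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_sw_score("HEAGAWGHEE", "PAWHEAE"))
})

test_that("Karlin-Altschul conversion reproduces the closed form", {
  expect_equal(ka_bits(12, 0.267, 0.041), 9.23, tolerance = 1e-2)
  expect_equal(ka_bits(0), -log(0.041) / log(2))
})

test_that("forward search recovers a planted coding region on either strand", {
  seqs <- c(r1 = "MKLVWHEAGAWGHEEMKVLPQRSTNDCE",
            r2 = "MKLVWHEAGAWGHEEMKVLPQRSTNDAE")
  profiles <- list(OG1 = build_profile(align_og(seqs), og_id = "OG1"))
  gc <- Biostrings::GENETIC_CODE
  cds <- paste(vapply(strsplit(seqs[[1]], "")[[1]],
                      function(a) names(gc)[gc == a][1L], ""),
               collapse = "")
  tr_fwd <- data.frame(transcript_id = "t1",
                       sequence = paste0("GGGGG", cds, "CCCCC"))
  cfg <- run_config(fwd_max_evalue = 1e-3)
  h <- forward_search(profiles, tr_fwd, cfg)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$nt_end - h$nt_start, 3L * (h$aa_end - h$aa_start))

  # reverse complement: hit on a negative frame with the same bit score
  tr_rev <- data.frame(transcript_id = "t1r",
                       sequence = revcomp(tr_fwd$sequence))
  h2 <- forward_search(profiles, tr_rev, cfg)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$bit_score, h$bit_score)
  # same forward-strand interval after mirroring
  L <- nchar(tr_fwd$sequence)
  expect_equal(h2$nt_start, L - h$nt_end)
  expect_equal(h2$nt_end, L - h$nt_start)

  expect_equal(nrow(forward_search(profiles,
                                   data.frame(transcript_id = character(),
                                              sequence = character()),
                                   cfg)), 0L)
})

test_that("forward-hit coordinates round-trip through translation", {
  cr <- clean_run()
  fwd <- cr$run$forward
  seqs <- setNames(cr$run$transcripts$sequence,
                   cr$run$transcripts$transcript_id)
  for (i in seq_len(nrow(fwd))) {
    nt <- substr(seqs[[fwd$transcript_id[i]]], fwd$nt_start[i] + 1L,
                 fwd$nt_end[i])
    if (fwd$strand[i] == "-") nt <- revcomp(nt)
    expect_equal(translate_nt(nt), fwd$aa_seq[i],
                 info = paste("hit", fwd$hit_id[i]))
  }
})

test_that("reverse search ranks the identical protein first", {
  prot <- data.frame(
    protein_id = c("hit", "d1", "d2"),
    sequence = c("MKLVWHAE", "GGGGGGGG", "PPPPPPPP"))
  r <- reverse_search("MKLVWHAE", prot, run_config())
  expect_equal(r$target_protein_id[r$rank == 1L], "hit")
  expect_equal(r$raw_score[1L], smith_waterman("MKLVWHAE", "MKLVWHAE")$score)
  expect_equal(r$bit_score[1L], ka_bits(r$raw_score[1L]))
  expect_error(reverse_search("", prot), "empty")
})

test_that("exact mode dominates heuristic mode and agrees when seeded", {
  set.seed(22)
  prot <- data.frame(protein_id = sprintf("p%02d", 1:10),
                     sequence = replicate(10, random_aa(30)))
  cfg_ex <- run_config(search_mode = "exact")
  cfg_he <- run_config(search_mode = "heuristic")
  for (rep in 1:10) {
    # query derived from a database protein so seeds exist
    src <- sample(10, 1)
    q <- substr(prot$sequence[src], 3, 25)
    ex <- reverse_search(q, prot, cfg_ex)
    he <- reverse_search(q, prot, cfg_he)
    expect_true(nrow(he) >= 1L)
    expect_equal(he$target_protein_id[1L], ex$target_protein_id[1L])
    # every heuristic score also appears in exact mode with equal value
    m <- match(he$target_protein_id, ex$target_protein_id)
    expect_false(anyNA(m))
    expect_equal(he$bit_score, ex$bit_score[m])
    # exact mode scans everything: at least as many hits
    expect_gte(nrow(ex), nrow(he))
  }
})

test_that("Smith-Waterman agrees with Biostrings' local aligner", {
  set.seed(23)
  mat <- blosum62()
  for (rep in 1:20) {
    a <- random_aa(sample(5:15, 1))
    b <- random_aa(sample(5:15, 1))
    ours <- smith_waterman(a, b)$score
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1))
    expect_equal(ours, max(0, ref), info = paste(a, b))
  }
})
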