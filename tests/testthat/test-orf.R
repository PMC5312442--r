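test_that("the guiding reference is the most similar group member", {
  set <- toy_set(list(OG1 = c(A = "p1", B = "p2", C = "p3")),
                 c(p1 = "MKVLWHEAGA", p2 = "MKVLWHEAGC", p3 = "PQRSTNDCEW"))
  a <- data.frame(og_id = "OG1", aa_seq = "MKVLWHEAGC")
  expect_equal(pick_reference(a, set)$protein_id, "p2")
  # argmax of brute-force scores over all members
  scores <- vapply(c("p1", "p2", "p3"), function(p)
    oracle_sw_score("MKVLWHEAGC",
                    set$proteins$sequence[set$proteins$protein_id == p]), 0)
  expect_equal(pick_reference(a, set)$score, max(scores))

  set1 <- toy_set(list(OG1 = c(A = "p1")), c(p1 = "MKVLWHEAGA"))
  expect_equal(pick_reference(a, set1)$protein_id, "p1")
})

test_that("a perfect coding sequence yields a frameshift-free ORF", {
  sk <- frameshift_align("MKV", "ATGAAAGTG")
  expect_true(sk$found)
  expect_equal(sk$aa, "MKV")
  expect_equal(sk$nt, "ATGAAAGTG")
  expect_equal(nrow(sk$frameshifts), 0L)
  expect_equal(translate_nt(sk$nt), sk$aa)
})

test_that("a planted extra base is excised as a frameshift event", {
  # tiny instance: the penalty must undercut the single downstream match
  cfg_soft <- run_config(frameshift_penalty = 3)
  sk <- frameshift_align("MKKV", "ATGAAAAAAGGTG", cfg_soft)
  expect_true(sk$found)
  expect_equal(sk$aa, "MKKV")
  expect_equal(nrow(sk$frameshifts), 1L)
  expect_equal(sk$frameshifts$size, 1L)
  expect_equal(nchar(sk$nt), 12L) # one of the 13 nt is excised
  expect_equal(translate_nt(sk$nt), "MKKV")
  # with a longer conserved flank the default penalty recovers the shift
  prot <- "MKKVWHAEMKVL"
  dna <- "ATGAAAAAAGGTGTGGCATGCTGAAATGAAAGTTCTG"
  sk2 <- frameshift_align(prot, dna)
  expect_true(sk2$found)
  expect_equal(translate_nt(sk2$nt), sk2$aa)
})

test_that("frameshift DP equals exhaustive enumeration on micro instances", {
  set.seed(41)
  for (rep in 1:12) {
    p <- random_aa(sample(1:2, 1))
    d <- random_dna(sample(3:8, 1))
    got <- frameshift_align(p, d)
    want <- oracle_frameshift_enum(p, d)
    expect_equal(if (got$found) got$score else 0, want,
                 info = paste(p, d))
  }
})

test_that("frameshift DP equals the independent DP on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    p <- random_aa(sample(2:6, 1))
    d <- random_dna(sample(6:24, 1))
    got <- frameshift_align(p, d)
    want <- oracle_frameshift_dp(p, d)
    expect_equal(if (got$found) got$score else 0, want,
                 info = paste(p, d))
    if (got$found) {
      expect_equal(translate_nt(got$nt), got$aa, info = paste(p, d))
    }
  }
})

test_that("ORF extension respects the coverage constraint", {
  # 10-aa hit region inside a longer clean reading frame
  aa_full <- "MKVLWHEAGAWGHEEMKVLP"
  gc <- Biostrings::GENETIC_CODE
  cds <- paste(vapply(strsplit(aa_full, "")[[1]],
                      function(a) names(gc)[gc == a][1L], ""),
               collapse = "")
  dna <- paste0("GG", cds, "TAAGG") # extension must stop at the TAA
  brh <- c(2L + 15L, 2L + 45L)      # codons 6..15
  sk <- frameshift_align(substr(aa_full, 6, 15), dna)
  orf <- extend_orf(sk, brh, dna, run_config(min_orf_coverage = 0.5))
  expect_equal(orf$aa, aa_full) # extended to the full frame, stop excluded
  expect_equal(orf$coverage, 10 / 20)
  expect_equal(translate_nt(orf$nt), orf$aa)
  expect_equal(sum(orf$segments$end - orf$segments$start) %/% 3L,
               nchar(orf$aa))

  # full coverage demanded: the ORF shrinks back to the hit region
  orf2 <- extend_orf(sk, brh, dna, run_config(min_orf_coverage = 1))
  expect_equal(nchar(orf2$aa), 10L)
  expect_equal(orf2$coverage, 1)

  # intermediate demand trims the extension until the ratio holds
  orf3 <- extend_orf(sk, brh, dna, run_config(min_orf_coverage = 0.8))
  expect_lte(nchar(orf3$aa), floor(10 / 0.8))
  expect_gte(orf3$coverage, 0.8)
})

test_that("planted frameshifts in a full fixture are corrected end to end", {
  fx <- sim_generate(sim_config(seed = 55L, n_ogs = 6L, n_ref_taxa = 3L,
                                frameshift_rate = 1, subst_prob = 0.03,
                                n_decoy_transcripts = 2L),
                     tempfile("fs"))
  run <- run_fixture(fx)
  expect_gt(nrow(run$assignments), 0L)
  orfs <- refine_orfs(run$assignments, run$set, run$transcripts)
  found <- !vapply(orfs, is.null, TRUE)
  expect_true(any(found))
  for (i in which(found)) {
    expect_equal(translate_nt(orfs[[i]]$nt), orfs[[i]]$aa)
    expect_gte(orfs[[i]]$coverage, run_config()$min_orf_coverage)
    expect_lte(orfs[[i]]$coverage, 1)
  }
  # at least one planted shift is recovered as an event
  expect_gt(sum(vapply(orfs[found],
                       function(o) nrow(o$frameshifts), 0L)), 0L)
})
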