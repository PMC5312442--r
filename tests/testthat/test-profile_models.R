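test_that("center-star alignment handles trivial and gapped cases", {
  a1 <- align_og(c(s1 = "MKV"))
  expect_equal(a1$ncols, 3L)
  expect_equal(unname(a1$rows), "MKV")

  a2 <- align_og(c(s1 = "MKV", s2 = "MKV"))
  expect_equal(unname(a2$rows), c("MKV", "MKV"))

  a3 <- align_og(c(long = "MKVL", short = "MKL"))
  expect_equal(a3$ncols, 4L)
  expect_equal(sum(strsplit(a3$rows[["short"]], "")[[1]] == "-"), 1L)
  expect_equal(gsub("-", "", a3$rows[["short"]]), "MKL")
  expect_equal(a3$rows[["long"]], "MKVL")
})

test_that("degapping any alignment row reproduces the input sequence", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    base <- random_aa(sample(10:30, 1))
    seqs <- setNames(vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      drop <- runif(length(s)) < 0.1
      paste(s[!drop], collapse = "")
    }, ""), paste0("q", seq_len(n)))
    al <- align_og(seqs)
    expect_true(all(nchar(al$rows) == al$ncols))
    for (nm in names(seqs)) {
      expect_equal(gsub("-", "", al$rows[[nm]]), unname(seqs[[nm]]))
    }
  }
})

test_that("profile construction matches the closed-form counts", {
  al <- align_og(c(a = "MK", b = "MK"))
  m <- build_profile(al, pseudocount = 1)
  expect_equal(m$nmatch, 2L)
  w <- 1
  expect_equal(unname(m$emis[1L, "M"]), (2 + w * (1 / 20)) / (2 + w))
  expect_equal(unname(rowSums(m$emis)), rep(1, 2), tolerance = 1e-12)

  # a column below the occupancy threshold is not a match state
  al2 <- structure(list(rows = c(a = "MA", b = "M-", c = "M-", d = "M-"),
                        ncols = 2L), class = "og_alignment")
  m2 <- build_profile(al2)
  expect_equal(m2$nmatch, 1L)
  expect_equal(m2$match_cols, 1L)

  # all-gap-ish alignment with zero match columns errors
  al3 <- structure(list(rows = c(a = "M---", b = "-A--", c = "--C-",
                                 d = "---D"), ncols = 4L),
                   class = "og_alignment")
  expect_error(build_profile(al3), "no match columns")
})

test_that("profile transition distributions are normalized", {
  set.seed(7)
  for (rep in 1:5) {
    m <- random_model(nmatch = sample(3:8, 1), nseq = sample(2:4, 1))
    tr <- m$trans
    M <- m$nmatch
    if (M > 1) {
      expect_equal(tr$tmm + tr$tmd + tr$tmi[seq_len(M - 1)],
                   rep(1, M - 1), tolerance = 1e-9)
      expect_equal(tr$tim + tr$tii[seq_len(M - 1)], rep(1, M - 1),
                   tolerance = 1e-9)
      expect_equal(tr$tdm + tr$tdd, rep(1, M - 1), tolerance = 1e-9)
    }
  }
})

test_that("profile building is deterministic", {
  seqs <- c(x = "MKVLWHEAG", y = "MKVLHEAG", z = "MKVWHEAG")
  m1 <- build_profile(align_og(seqs))
  m2 <- build_profile(align_og(seqs[c(3, 1, 2)]))
  expect_identical(m1$emis, m2$emis)
  expect_identical(m1$trans, m2$trans)
})

test_that("the consensus sequence outscores an unrelated one", {
  m <- build_profile(align_og(c(a = "MKLVWH", b = "MKLVWH", c = "MKLVWH")))
  s1 <- score_sequence(m, "MKLVWH")
  s2 <- score_sequence(m, "AAAAAA")
  expect_gt(s1$bits, s2$bits)
  expect_gte(s1$seq_end, s1$seq_start)
  expect_gte(s1$hmm_end, s1$hmm_start)
  # E-value definition
  s3 <- score_sequence(m, "MKLVWH", db_residues = 1000)
  expect_equal(s3$evalue, 1000 * 2^(-s3$bits))
})

test_that("local Viterbi equals exhaustive path enumeration on tiny models", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_model(nmatch = sample(2:3, 1), nseq = 2,
                      len = sample(2:4, 1))
    q <- random_aa(sample(2:4, 1))
    got <- score_sequence(m, q)$bits
    expect_equal(got, oracle_viterbi_enum(m, q), tolerance = 1e-9,
                 info = sprintf("rep %d query %s", rep, q))
  }
})

test_that("local Viterbi equals the independent DP on larger random models", {
  set.seed(12)
  for (rep in 1:60) {
    m <- random_model(nmatch = sample(3:8, 1), nseq = sample(2:4, 1),
                      len = sample(4:9, 1))
    q <- random_aa(sample(3:10, 1))
    expect_equal(score_sequence(m, q)$bits, oracle_viterbi_dp(m, q),
                 tolerance = 1e-9,
                 info = sprintf("rep %d query %s", rep, q))
  }
})

test_that("appending unrelated flanks never lowers the local score", {
  set.seed(13)
  for (rep in 1:10) {
    m <- random_model(nmatch = 6, nseq = 3, len = 8)
    core <- random_aa(8)
    base <- score_sequence(m, core)$bits
    padded <- score_sequence(m, paste0(random_aa(5), core, random_aa(5)))$bits
    expect_gte(padded, base - 1e-9)
  }
})
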