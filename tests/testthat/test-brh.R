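make_pair <- function(og, bits, rev_targets, rev_bits,
                      transcript = "t1", nt = c(0L, 300L)) {
  fwd <- data.frame(hit_id = 1L, og_id = og, transcript_id = transcript,
                    frame = "+1", strand = "+", bit_score = bits,
                    evalue = 1e-10, aa_start = nt[1L] %/% 3L,
                    aa_end = nt[2L] %/% 3L, hmm_start = 0L,
                    hmm_end = (nt[2L] - nt[1L]) %/% 3L,
                    nt_start = nt[1L], nt_end = nt[2L], aa_seq = "MKV",
                    stringsAsFactors = FALSE)
  rev <- if (length(rev_targets)) {
    data.frame(hit_id = 1L, target_protein_id = rev_targets,
               raw_score = 10, bit_score = rev_bits, evalue = 1e-8,
               aln_len = 10L, rank = seq_along(rev_targets),
               stringsAsFactors = FALSE)
  } else empty_rev_df()
  list(fwd = fwd, rev = rev)
}

brh_set <- function() {
  toy_set(list(OG1 = c(A = "p1", B = "p2"), OG2 = c(A = "p3", B = "p9")),
          c(p1 = "MKVLWHEAGA", p2 = "MKVLWHEAGC", p3 = "PQRSTNDCEW",
            p9 = "PQRSTNDCEF"))
}

test_that("collation orders candidates deterministically by forward bits", {
  fwd <- data.frame(
    hit_id = 1:4, og_id = c("OG2", "OG1", "OG1", "OG2"),
    transcript_id = c("t4", "t2", "t1", "t3"), frame = "+1", strand = "+",
    bit_score = c(10, 90, 100, 90), evalue = c(1e-2, 1e-6, 1e-8, 1e-6),
    aa_start = 0L, aa_end = c(10L, 30L, 40L, 30L), hmm_start = 0L,
    hmm_end = 10L, nt_start = 0L, nt_end = 30L, aa_seq = "M",
    stringsAsFactors = FALSE)
  rev <- empty_rev_df(); rev$hit_id <- integer()
  ord1 <- vapply(collate(fwd, rev), function(p) p$fwd$transcript_id, "")
  expect_equal(ord1, c("t1", "t2", "t3", "t4"))
  # permutation invariance
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    ord2 <- vapply(collate(fwd[perm, ], rev),
                   function(p) p$fwd$transcript_id, "")
    expect_equal(ord2, ord1)
  }
  expect_length(collate(fwd[0, ], rev), 0L)
})

test_that("the reciprocal criterion accepts only in-group rank-1 hits", {
  set <- brh_set()
  p <- make_pair("OG1", 100, c("p2", "p9"), c(50, 40))
  expect_true(evaluate_brh(p, set)$accept)

  p2 <- make_pair("OG1", 100, c("p9", "p2"), c(50, 40))
  r2 <- evaluate_brh(p2, set)
  expect_false(r2$accept)
  expect_equal(r2$reason, "best_hit_outside_og")

  p3 <- make_pair("OG1", 100, character(), numeric())
  expect_equal(evaluate_brh(p3, set)$reason, "no_reverse_hit")

  # rank-1 tie: lenient accepts if one tied protein is a member
  p4 <- make_pair("OG1", 100, c("p9", "p2"), c(50, 50))
  expect_true(evaluate_brh(p4, set)$accept)
  expect_false(evaluate_brh(p4, set, strict = TRUE)$accept)
})

test_that("greedy assignment claims regions by descending score", {
  set <- brh_set()
  # same region contested by two groups: only the stronger one wins
  a <- make_pair("OG1", 100, "p2", 50)
  b <- make_pair("OG2", 80, "p3", 45)
  b$fwd$hit_id <- 2L; b$rev$hit_id <- 2L
  fwd <- rbind(a$fwd, b$fwd); rev <- rbind(a$rev, b$rev)
  res <- assign_all(collate(fwd, rev), set)
  expect_equal(res$assignments$og_id, "OG1")
  expect_equal(res$rejections$reason, "region_already_claimed")

  # disjoint regions on one transcript: both (chimera-style) are kept
  b2 <- make_pair("OG2", 80, "p3", 45, nt = c(600L, 900L))
  b2$fwd$hit_id <- 2L; b2$rev$hit_id <- 2L
  res2 <- assign_all(collate(rbind(a$fwd, b2$fwd), rbind(a$rev, b2$rev)),
                     set)
  expect_equal(sort(res2$assignments$og_id), c("OG1", "OG2"))

  # whole-transcript ledger blocks even disjoint second claims
  res3 <- assign_all(collate(rbind(a$fwd, b2$fwd), rbind(a$rev, b2$rev)),
                     set, run_config(ledger = "transcript"))
  expect_equal(res3$assignments$og_id, "OG1")
  expect_equal(res3$rejections$reason, "region_already_claimed")
})

test_that("assignment matches the independent greedy oracle on random tables", {
  set.seed(31)
  for (rep in 1:30) {
    rc <- random_candidates()
    res <- assign_all(collate(rc$fwd, rc$rev), rc$set)
    got <- sort(paste(res$assignments$transcript_id, res$assignments$og_id,
                      res$assignments$nt_start, sep = "/"))
    cands <- rc$fwd
    cands$bits <- cands$bit_score
    cands$brh_ok <- vapply(seq_len(nrow(cands)), function(i) {
      rv <- rc$rev[rc$rev$hit_id == cands$hit_id[i], ]
      nrow(rv) > 0 &&
        isTRUE(og_of(rc$set, rv$target_protein_id[which.max(rv$bit_score)]) ==
                 cands$og_id[i])
    }, TRUE)
    expect_equal(got, oracle_greedy(cands), info = paste("table", rep))
  }
})

test_that("assignment row order never leaks into results", {
  set.seed(32)
  rc <- random_candidates()
  base <- assign_all(collate(rc$fwd, rc$rev), rc$set)$assignments
  for (rep in 1:5) {
    perm <- sample(nrow(rc$fwd))
    res <- assign_all(collate(rc$fwd[perm, ], rc$rev), rc$set)$assignments
    expect_equal(res[order(res$hit_id), ], base[order(base$hit_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("re-evaluation from the store is deterministic and threshold-sensitive", {
  cr <- clean_run()
  st <- withr::local_tempdir()
  store_create(st)
  store_write_ortholog_set(st, cr$run$set)
  store_write_hits(st, cr$run$transcripts, cr$run$forward, cr$run$reverse,
                   run_config())
  r1 <- brh_reevaluate(st, run_config())
  r2 <- brh_reevaluate(st, run_config())
  expect_identical(r1, r2)
  expect_equal(nrow(r1$assignments), nrow(cr$run$assignments))

  # raising the forward threshold above the maximum kills all assignments
  top <- max(cr$run$forward$bit_score)
  r3 <- brh_reevaluate(st, run_config(fwd_min_bits = top + 1))
  expect_equal(nrow(r3$assignments), 0L)

  # tightening across a grid only ever shrinks the assignment set
  keys <- function(r) paste(r$assignments$transcript_id,
                            r$assignments$og_id, r$assignments$nt_start)
  prev <- keys(r1)
  for (thr in quantile(cr$run$forward$bit_score, c(.25, .5, .75, 1))) {
    cur <- keys(brh_reevaluate(st, run_config(fwd_min_bits = thr)))
    expect_true(all(cur %in% prev), info = paste("threshold", thr))
    prev <- cur
  }
  # a store without hit tables fails loudly
  st2 <- withr::local_tempdir()
  store_create(st2)
  expect_error(brh_reevaluate(st2, run_config()), "no hits")
})
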