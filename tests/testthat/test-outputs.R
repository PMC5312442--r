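output_fixture <- function() {
  fx <- sim_generate(sim_config(seed = 77L, n_ogs = 4L, n_ref_taxa = 3L,
                                subst_prob = 0.04,
                                n_decoy_transcripts = 2L),
                     tempfile("outfx"))
  run <- run_fixture(fx)
  orfs <- refine_orfs(run$assignments, run$set, run$transcripts)
  list(run = run, orfs = orfs)
}

test_that("per-group FASTA pairs correspond record by record", {
  ofx <- output_fixture()
  outdir <- withr::local_tempdir()
  write_og_fastas(ofx$run$assignments, ofx$orfs, outdir,
                  ofx$run$transcripts, taxon = "target")
  aa_files <- sort(list.files(outdir, "\\.aa\\.fa$", full.names = TRUE))
  expect_gt(length(aa_files), 0L)
  for (af in aa_files) {
    nf <- sub("\\.aa\\.fa$", ".nt.fa", af)
    expect_true(file.exists(nf))
    aa <- Biostrings::readAAStringSet(af)
    nt <- Biostrings::readDNAStringSet(nf)
    expect_equal(names(aa), names(nt)) # identical headers, identical order
    for (k in seq_along(aa)) {
      expect_equal(translate_nt(as.character(nt[[k]])),
                   as.character(aa[[k]]))
    }
    # headers carry og|taxon|transcript|span|strand
    expect_true(all(lengths(strsplit(names(aa), "|", fixed = TRUE)) == 5L))
  }
  # round-trip: emitted sequences are exactly the ORF results
  emitted <- unlist(lapply(aa_files, function(af)
    as.character(Biostrings::readAAStringSet(af))))
  kept <- ofx$orfs[!vapply(ofx$orfs, is.null, TRUE)]
  expect_setequal(unname(emitted), vapply(kept, function(o) o$aa, ""))
})

test_that("overlap flags form transitive groups over profile intervals", {
  a <- data.frame(og_id = "OG1", transcript_id = paste0("t", 1:3),
                  hmm_start = c(0L, 40L, 80L), hmm_end = c(50L, 90L, 120L))
  ov <- flag_overlaps(a)
  expect_equal(length(unique(ov)), 1L) # one chained group of three
  expect_false(anyNA(ov))

  b <- data.frame(og_id = "OG1", transcript_id = c("t1", "t2"),
                  hmm_start = c(0L, 60L), hmm_end = c(40L, 100L))
  expect_true(all(is.na(flag_overlaps(b)))) # disjoint: no flags

  c_ <- data.frame(og_id = "OG1", transcript_id = c("t1", "t2"),
                   hmm_start = c(0L, 40L), hmm_end = c(60L, 100L))
  ovc <- flag_overlaps(c_)
  expect_equal(ovc[1L], ovc[2L])
})

test_that("concatenation keeps the higher-scoring section on overlap", {
  orfs <- list(list(aa = "MKVLW", nt = "ATGAAAGTTCTGTGG"),
               list(aa = "HEAGA", nt = "CATGAAGCTGGTGCT"))
  a <- data.frame(og_id = "OG1", transcript_id = c("t1", "t2"),
                  hmm_start = c(0L, 5L), hmm_end = c(5L, 10L),
                  fwd_bits = c(80, 60))
  cc <- concatenate_og(a, orfs)
  expect_equal(cc$aa, "MKVLWHEAGA")
  expect_equal(nchar(cc$nt), 30L)
  expect_equal(cc$parts, c("t1", "t2"))

  # fully overlapping: only the 80-bit section survives
  a2 <- data.frame(og_id = "OG1", transcript_id = c("t1", "t2"),
                   hmm_start = c(0L, 0L), hmm_end = c(5L, 5L),
                   fwd_bits = c(80, 60))
  cc2 <- concatenate_og(a2, orfs)
  expect_equal(cc2$aa, "MKVLW")
  expect_equal(cc2$parts, "t1")

  # single section is the identity
  cc3 <- concatenate_og(a[1L, ], orfs[1L])
  expect_equal(cc3$aa, "MKVLW")
})

test_that("run summaries count assignments, coverage and rejections", {
  ofx <- output_fixture()
  rep1 <- list(report = report_table(ofx$run$assignments, ofx$orfs),
               rejections = ofx$run$rejections)
  s <- summarize_runs(list(runA = rep1, runB = rep1))
  expect_equal(s$summary$n_assigned, rep(nrow(rep1$report), 2L))
  expect_identical(s$presence[, 1L], s$presence[, 2L])
  expect_equal(sum(s$presence[, 1L]), length(unique(rep1$report$og_id)))

  empty <- list(report = report_table(orthomapr:::empty_assignments(),
                                      list()),
                rejections = ofx$run$rejections[0L, ])
  s2 <- summarize_runs(list(full = rep1, none = empty))
  expect_equal(s2$summary$n_assigned[2L], 0L)
  expect_true(all(s2$presence[, "none"] == 0L))
})

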