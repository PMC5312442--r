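# Shared fixture builders. Everything is generated in code at test time.

# minimal ortholog set built directly from member/sequence specs
toy_set <- function(members, sequences, extra_proteins = NULL) {
  groups <- lapply(names(members), function(og) {
    m <- members[[og]]
    list(og_id = og,
         members = data.frame(taxon = names(m), protein_id = unname(m),
                              stringsAsFactors = FALSE))
  })
  names(groups) <- names(members)
  ids <- unlist(lapply(members, unname), use.names = FALSE)
  taxa <- unlist(lapply(members, names), use.names = FALSE)
  proteins <- data.frame(protein_id = ids, taxon = taxa,
                         sequence = unname(sequences[ids]),
                         length = nchar(unname(sequences[ids])),
                         description = ids, stringsAsFactors = FALSE)
  if (!is.null(extra_proteins)) proteins <- rbind(proteins, extra_proteins)
  build_ortholog_set(groups, proteins, policy = "strict")
}

# run the searches + assignment fully in memory on a generated fixture
run_fixture <- function(fx, cfg = run_config()) {
  groups <- parse_og_table(fx$og_table)
  proteins <- do.call(rbind, lapply(names(fx$proteomes), function(tx)
    load_rgs_fasta(fx$proteomes[[tx]], tx)))
  set <- suppressWarnings(
    build_ortholog_set(groups, proteins, policy = "strict"))
  seq_of <- setNames(set$proteins$sequence, set$proteins$protein_id)
  profiles <- lapply(set$groups, function(g)
    build_profile(align_og(seq_of[sort(g$members$protein_id)]),
                  og_id = g$og_id))
  transcripts <- fx$transcripts_df
  fwd <- forward_search(profiles, transcripts, cfg)
  db_res <- sum(nchar(set$proteins$sequence))
  rev <- if (nrow(fwd)) do.call(rbind, lapply(seq_len(nrow(fwd)),
    function(i) {
      r <- reverse_search(fwd$aa_seq[i], set$proteins, cfg, db_res)
      if (nrow(r)) cbind(hit_id = fwd$hit_id[i], r) else NULL
    })) else NULL
  if (is.null(rev)) rev <- cbind(hit_id = integer(), empty_rev_df())
  res <- assign_all(collate(fwd, rev), set, cfg)
  list(set = set, profiles = profiles, transcripts = transcripts,
       forward = fwd, reverse = rev, assignments = res$assignments,
       rejections = res$rejections)
}

empty_rev_df <- function() {
  data.frame(target_protein_id = character(), raw_score = numeric(),
             bit_score = numeric(), evalue = numeric(),
             aln_len = integer(), rank = integer(),
             stringsAsFactors = FALSE)
}

# the clean benchmark fixture (20 groups, 4 reference taxa, 5% divergence,
# no planted errors), computed once per test session
clean_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- sim_generate(sim_config(seed = 101L, n_ogs = 20L,
                                    n_ref_taxa = 4L, subst_prob = 0.05),
                         tempfile("clean"))
      cache <<- list(fx = fx, run = run_fixture(fx))
    }
    cache
  }
})

# synthetic candidate tables exercising assign_all against the greedy oracle
random_candidates <- function(n_og = 5L, n_tr = 8L) {
  ogs <- paste0("OG", seq_len(n_og))
  # one reference protein per group; queries irrelevant for this path
  seqs <- setNames(replicate(n_og, random_aa(12)), paste0("p", seq_len(n_og)))
  members <- lapply(seq_len(n_og), function(i)
    setNames(paste0("p", i), "A"))
  names(members) <- ogs
  set <- toy_set(members, seqs)
  ncand <- sample(3:14, 1L)
  fwd <- data.frame(
    hit_id = seq_len(ncand),
    og_id = sample(ogs, ncand, replace = TRUE),
    transcript_id = sample(paste0("t", seq_len(n_tr)), ncand,
                           replace = TRUE),
    frame = "+1", strand = "+",
    bit_score = round(runif(ncand, 10, 200), 6),
    evalue = runif(ncand, 0, 1e-6),
    stringsAsFactors = FALSE)
  fwd$aa_start <- sample(0:50, ncand, replace = TRUE)
  fwd$aa_end <- fwd$aa_start + sample(5:40, ncand, replace = TRUE)
  fwd$hmm_start <- 0L; fwd$hmm_end <- fwd$aa_end - fwd$aa_start
  fwd$nt_start <- 3L * fwd$aa_start
  fwd$nt_end <- 3L * fwd$aa_end
  fwd$aa_seq <- vapply(fwd$aa_end - fwd$aa_start, random_aa, "")
  brh_ok <- runif(ncand) < 0.7
  rev <- do.call(rbind, lapply(seq_len(ncand), function(i) {
    tgt <- if (brh_ok[i]) set$groups[[fwd$og_id[i]]]$members$protein_id[1L]
           else paste0("p", (match(fwd$og_id[i], ogs) %% n_og) + 1L)
    data.frame(hit_id = i, target_protein_id = tgt,
               raw_score = 50, bit_score = round(runif(1, 20, 80), 6),
               evalue = 1e-8, aln_len = 20L, rank = 1L,
               stringsAsFactors = FALSE)
  }))
  list(set = set, fwd = fwd, rev = rev, brh_ok = brh_ok)
}
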