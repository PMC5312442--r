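# The three pipeline stages over a run store: manage (build and persist
# the ortholog set and profiles), analyze (run and persist the searches),
# report (assign, refine ORFs and write outputs from stored hits only).

#' Manage: build and persist the ortholog set and profile models
#'
#' @param store store directory (created if needed)
#' @param og_table path to the tab-delimited ortholog-group table
#' @param proteomes named character vector of proteome FASTA paths, names
#'   are taxon labels
#' @param config a [run_config()]
#' @param collapse_isoforms see [build_ortholog_set()]
#' @return the `ortholog_set`, invisibly
#' @export
og_manage <- function(store, og_table, proteomes, config = run_config(),
                      collapse_isoforms = FALSE) {
  cfg <- as_run_config(config)
  store_create(store)
  groups <- parse_og_table(og_table)
  stopifnot(!is.null(names(proteomes)), all(nzchar(names(proteomes))))
  proteins <- do.call(rbind, lapply(names(proteomes), function(tx)
    load_rgs_fasta(proteomes[[tx]], tx)))
  set <- build_ortholog_set(groups, proteins, policy = cfg$og_policy,
                            isoform_identity = cfg$isoform_identity,
                            collapse_isoforms = collapse_isoforms)
  seq_of <- setNames(set$proteins$sequence, set$proteins$protein_id)
  profiles <- lapply(set$groups, function(g) {
    aln <- align_og(seq_of[sort(g$members$protein_id)],
                    gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    build_profile(aln, pseudocount = cfg$pseudocount,
                  match_occupancy = cfg$match_occupancy, og_id = g$og_id)
  })
  store_write_ortholog_set(store, set)
  store_write_profiles(store, profiles)
  message(sprintf("manage: %d groups, %d proteins, %d taxa",
                  length(set$groups), nrow(set$proteins),
                  length(set$taxa)))
  invisible(set)
}

read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(transcript_id = ids, sequence = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analyze: run and persist the forward and reverse searches
#'
#' @param store store directory prepared by [og_manage()]
#' @param transcript_fasta path to the nucleotide transcript FASTA
#' @param config a [run_config()]
#' @return list with the hit tables, invisibly
#' @export
og_analyze <- function(store, transcript_fasta, config = run_config()) {
  cfg <- as_run_config(config)
  store_open(store)
  profiles <- store_read_profiles(store)
  set <- store_read_ortholog_set(store)
  transcripts <- read_transcript_fasta(transcript_fasta)
  fwd <- forward_search(profiles, transcripts, cfg)
  db_res <- sum(nchar(set$proteins$sequence))
  rev <- if (nrow(fwd)) do.call(rbind, lapply(seq_len(nrow(fwd)),
    function(i) {
      r <- reverse_search(fwd$aa_seq[i], set$proteins, cfg, db_res)
      if (nrow(r)) cbind(hit_id = fwd$hit_id[i], r) else NULL
    })) else NULL
  if (is.null(rev)) rev <- cbind(hit_id = integer(), empty_reverse_hits())
  store_write_hits(store, transcripts, fwd, rev, cfg)
  message(sprintf("analyze: %d transcripts, %d forward hits, %d reverse hits",
                  nrow(transcripts), nrow(fwd), nrow(rev)))
  invisible(list(forward = fwd, reverse = rev))
}

#' Report: assign, refine ORFs and write outputs from stored hits
#'
#' Operates exclusively on persisted search results, so it can be re-run
#' with a different configuration without repeating the searches. Output
#' is deterministic: identical store and configuration give byte-identical
#' files.
#'
#' @param store store directory with persisted hits
#' @param outdir output directory for the report and FASTA files
#' @param config a [run_config()]; `NULL` uses the configuration stored at
#'   analysis time
#' @return list with `assignments`, `rejections`, `report`, `orfs`,
#'   invisibly
#' @export
og_report <- function(store, outdir, config = NULL) {
  store_open(store)
  hits <- store_read_hits(store)
  cfg <- if (is.null(config)) hits$config else as_run_config(config)
  set <- store_read_ortholog_set(store)
  res <- brh_reevaluate(store, cfg)
  orfs <- refine_orfs(res$assignments, set, hits$transcripts, cfg)
  rep <- report_table(res$assignments, orfs)
  ord <- order(rep$og_id, rep$transcript_id, rep$nt_start)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(rep[ord, , drop = FALSE], file.path(outdir, "report.tsv"))
  write_tsv(res$rejections, file.path(outdir, "rejections.tsv"))
  write_og_fastas(res$assignments, orfs, file.path(outdir, "fasta"),
                  hits$transcripts, taxon = cfg$target_taxon)
  for (og in sort(unique(res$assignments$og_id))) {
    idx <- which(res$assignments$og_id == og)
    if (!any(!vapply(orfs[idx], is.null, TRUE))) next
    cc <- concatenate_og(res$assignments[idx, , drop = FALSE], orfs[idx])
    hd <- paste0(og, "|", cfg$target_taxon, "|",
                 paste(cc$parts, collapse = "+"))
    write_fasta(cc$aa, hd, file.path(outdir, paste0(og, ".concat.aa.fa")))
    write_fasta(cc$nt, hd, file.path(outdir, paste0(og, ".concat.nt.fa")))
  }
  store_write_assignments(store, res$assignments, res$rejections)
  message(sprintf(
    "report: %d assignments in %d groups, %d rejections (%s)",
    nrow(res$assignments), length(unique(res$assignments$og_id)),
    nrow(res$rejections),
    paste(names(table(res$rejections$reason)),
          table(res$rejections$reason), sep = "=", collapse = ", ")))
  invisible(list(assignments = res$assignments,
                 rejections = res$rejections, report = rep[ord, ],
                 orfs = orfs))
}
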