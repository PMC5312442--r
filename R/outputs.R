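# The "reporter" outputs: per-group amino-acid and nucleotide FASTA with
# 1:1 record correspondence, per-group concatenation, tabular reports,
# overlap flags, and multi-run summaries.

fasta_header <- function(og, taxon, transcript, nt_start, nt_end, strand,
                         sep = "|") {
  paste(og, taxon, transcript,
        paste0(nt_start + 1L, "-", nt_end), strand, sep = sep)
}

write_fasta <- function(seqs, headers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", headers[i]), seqs[i]), con)
  }
  invisible(path)
}

# forward-strand nt span of an ORF (its segments live on the
# strand-resolved sequence)
orf_forward_span <- function(orf, strand, nt_len) {
  if (strand == "+") c(orf$dna_start, orf$dna_end)
  else c(nt_len - orf$dna_end, nt_len - orf$dna_start)
}

#' Write per-group amino-acid and nucleotide FASTA files
#'
#' One `<og>.aa.fa` and one `<og>.nt.fa` per group with ORF results;
#' records correspond 1:1 and appear in identical order. Headers are
#' `og|taxon|transcript|start-end|strand` with 1-based inclusive
#' forward-strand coordinates of the ORF.
#'
#' @param assignments assignments data.frame
#' @param orfs list from [refine_orfs()] (parallel to assignment rows)
#' @param outdir output directory
#' @param transcripts data.frame `transcript_id`, `sequence` (for
#'   strand-aware coordinates)
#' @param taxon target-taxon label for headers
#' @param sep header field separator
#' @return data.frame of written records, invisibly
#' @export
write_og_fastas <- function(assignments, orfs, outdir, transcripts,
                            taxon = "target", sep = "|") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  nt_len <- setNames(nchar(transcripts$sequence), transcripts$transcript_id)
  keep <- which(!vapply(orfs, is.null, TRUE))
  if (!length(keep)) return(invisible(data.frame()))
  recs <- do.call(rbind, lapply(keep, function(i) {
    a <- assignments[i, ]
    span <- orf_forward_span(orfs[[i]], a$strand, nt_len[[a$transcript_id]])
    data.frame(og_id = a$og_id, transcript_id = a$transcript_id,
               strand = a$strand, nt_start = span[1L], nt_end = span[2L],
               aa = orfs[[i]]$aa, nt = orfs[[i]]$nt, row = i,
               stringsAsFactors = FALSE)
  }))
  recs <- recs[order(recs$og_id, recs$transcript_id, recs$nt_start), ,
               drop = FALSE]
  for (og in unique(recs$og_id)) {
    r <- recs[recs$og_id == og, , drop = FALSE]
    h <- fasta_header(r$og_id, taxon, r$transcript_id, r$nt_start,
                      r$nt_end, r$strand, sep)
    write_fasta(r$aa, h, file.path(outdir, paste0(og, ".aa.fa")))
    write_fasta(r$nt, h, file.path(outdir, paste0(og, ".nt.fa")))
  }
  invisible(recs)
}

#' Flag overlapping assignments within each group
#'
#' Transcripts assigned to one group whose profile column intervals
#' intersect share an overlap-group id (transitive closure); they may be
#' alternative transcripts or assembly artifacts, which are reported but
#' deliberately not classified.
#'
#' @param assignments assignments data.frame
#' @return character vector of overlap-group ids (`NA` for assignments
#'   overlapping nothing), parallel to the rows
#' @export
flag_overlaps <- function(assignments) {
  n <- nrow(assignments)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  for (og in unique(assignments$og_id)) {
    idx <- which(assignments$og_id == og)
    if (length(idx) < 2L) next
    parent <- seq_along(idx)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(length(idx) - 1L)) {
      for (j in seq((i + 1L), length(idx))) {
        a <- assignments[idx[i], ]; b <- assignments[idx[j], ]
        if (min(a$hmm_end, b$hmm_end) > max(a$hmm_start, b$hmm_start)) {
          parent[find(j)] <- find(i)
        }
      }
    }
    roots <- vapply(seq_along(idx), find, 0L)
    for (r in unique(roots)) {
      grp <- which(roots == r)
      if (length(grp) > 1L) {
        out[idx[grp]] <- paste0(og, ":", min(grp))
      }
    }
  }
  out
}

#' Concatenate the assigned sections of one group
#'
#' Sections are ordered by profile column start; of two sections whose
#' profile intervals overlap, the one with the higher forward bit score is
#' kept. Retained sections are joined with the configured spacers.
#'
#' @param assignments assignment rows of one group
#' @param orfs matching list of `orf_result`
#' @param aa_spacer,nt_spacer spacer strings (default empty)
#' @return list `aa`, `nt`, `parts` (transcript ids in join order)
#' @export
concatenate_og <- function(assignments, orfs, aa_spacer = "",
                           nt_spacer = "") {
  keep <- which(!vapply(orfs, is.null, TRUE))
  stopifnot(length(keep) >= 1L)
  a <- assignments[keep, , drop = FALSE]
  a$.orf <- keep
  a <- a[order(a$hmm_start, a$transcript_id), , drop = FALSE]
  sel <- integer()
  for (i in seq_len(nrow(a))) {
    clash <- FALSE
    for (s in sel) {
      if (min(a$hmm_end[i], a$hmm_end[s]) >
          max(a$hmm_start[i], a$hmm_start[s])) {
        clash <- TRUE
        if (a$fwd_bits[i] > a$fwd_bits[s]) sel[sel == s] <- i
        break
      }
    }
    if (!clash) sel <- c(sel, i)
  }
  sel <- sort(unique(sel))
  list(aa = paste(vapply(a$.orf[sel], function(k) orfs[[k]]$aa, ""),
                  collapse = aa_spacer),
       nt = paste(vapply(a$.orf[sel], function(k) orfs[[k]]$nt, ""),
                  collapse = nt_spacer),
       parts = a$transcript_id[sel])
}

#' Tabular report of all assignments
#'
#' One row per assignment with 1-based inclusive coordinates, search
#' scores, ORF coverage, frameshift counts and overlap-group flags.
#'
#' @param assignments assignments data.frame
#' @param orfs list from [refine_orfs()]
#' @return report data.frame
#' @export
report_table <- function(assignments, orfs) {
  ov <- flag_overlaps(assignments)
  n <- nrow(assignments)
  data.frame(
    og_id = assignments$og_id,
    transcript_id = assignments$transcript_id,
    strand = assignments$strand,
    nt_start = assignments$nt_start + 1L,
    nt_end = assignments$nt_end,
    aa_start = assignments$aa_start + 1L,
    aa_end = assignments$aa_end,
    fwd_bits = round(assignments$fwd_bits, 4L),
    fwd_evalue = signif(assignments$fwd_evalue, 6L),
    rev_protein_id = assignments$rev_protein_id,
    rev_bits = round(assignments$rev_bits, 4L),
    coverage = vapply(seq_len(n), function(i)
      if (is.null(orfs[[i]])) NA_real_ else
        round(orfs[[i]]$coverage, 4L), 0),
    n_frameshifts = vapply(seq_len(n), function(i)
      if (is.null(orfs[[i]])) NA_integer_ else
        nrow(orfs[[i]]$frameshifts), 0L),
    orf_found = !vapply(orfs, is.null, TRUE),
    overlap_group = ov,
    stringsAsFactors = FALSE)
}

#' Summarize several completed runs
#'
#' @param reports named list of run outputs, each
#'   `list(report = report_table df, rejections = df)`
#' @return list with `summary` (per-run counts) and `presence`
#'   (group x run 0/1 matrix)
#' @export
summarize_runs <- function(reports) {
  stopifnot(length(reports) >= 1L)
  runs <- names(reports)
  if (is.null(runs)) runs <- paste0("run", seq_along(reports))
  ogs <- sort(unique(unlist(lapply(reports, function(r) r$report$og_id))))
  presence <- matrix(0L, nrow = length(ogs), ncol = length(runs),
                     dimnames = list(ogs, runs))
  summ <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]$report
    rj <- reports[[i]]$rejections
    if (nrow(rp)) presence[unique(rp$og_id), i] <<- 1L
    reasons <- table(factor(rj$reason, levels = c(
      "no_reverse_hit", "best_hit_outside_og", "region_already_claimed")))
    data.frame(run = runs[i], n_ogs = length(unique(rp$og_id)),
               n_assigned = nrow(rp),
               mean_coverage = if (nrow(rp)) mean(rp$coverage, na.rm = TRUE)
               else NA_real_,
               rej_no_reverse_hit = as.integer(reasons[1L]),
               rej_best_hit_outside_og = as.integer(reasons[2L]),
               rej_region_already_claimed = as.integer(reasons[3L]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, presence = presence)
}
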