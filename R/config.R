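#' Run configuration
#'
#' All tunable search and evaluation parameters of the pipeline. The whole
#' configuration is serialized verbatim into the run store so that any run
#' can be reproduced, and so that stored search results can be re-evaluated
#' under different thresholds without repeating the searches.
#'
#' @param fwd_min_bits minimum profile-HMM bit score for a forward hit
#' @param fwd_max_evalue maximum E-value for a forward hit
#' @param rev_min_bits minimum bit score for a reverse (protein database) hit
#' @param max_overlap tolerated overlap, in amino acids, between an accepted
#'   region and a previously claimed region before a candidate is rejected
#' @param min_orf_coverage minimum fraction of the final ORF length (in aa)
#'   that the best-reciprocal-hit region must cover; extensions beyond the
#'   hit region are trimmed until this holds
#' @param frameshift_penalty cost (half-bits, positive) per frameshift event
#'   in protein-guided ORF inference
#' @param stop_penalty cost (half-bits, positive) for an emitted stop codon
#' @param gap_open,gap_extend affine gap costs (half-bits) used by all
#'   Smith-Waterman style alignments
#' @param lambda,K Karlin-Altschul parameters converting raw Smith-Waterman
#'   scores to bit scores via `(lambda * S - log(K)) / log(2)`; defaults are
#'   the conventional gapped BLOSUM62 values
#' @param search_mode `"exact"` scans every database protein with full
#'   Smith-Waterman; `"heuristic"` restricts the scan to proteins sharing
#'   seed words with the query (BLAST-like)
#' @param seed_len word length for heuristic seeding
#' @param two_hit require two seed words on the same diagonal within
#'   `two_hit_window` before a database protein is aligned
#' @param two_hit_window diagonal window for the two-hit rule
#' @param ledger region-ledger granularity: `"section"` claims nucleotide
#'   intervals so a transcript may host several non-overlapping assignments;
#'   `"transcript"` claims whole transcripts
#' @param strict_brh if `TRUE`, a rank-1 bit-score tie in the reverse search
#'   is accepted only when all tied proteins belong to the ortholog group;
#'   otherwise one suffices
#' @param pseudocount pseudocount weight for profile estimation
#' @param match_occupancy minimum residue occupancy for an alignment column
#'   to become a profile match state
#' @param stop_lod profile emission log-odds (bits) assigned to in-frame
#'   stop symbols; mildly negative so assembly errors do not void a hit
#' @param isoform_identity pairwise identity above which two same-taxon
#'   reference proteins in one group are flagged as potential isoforms
#' @param min_hit_aa minimum translated-fragment length re-examined when
#'   searching for additional non-overlapping forward hits
#' @param max_hits_per_frame cap on forward hits per (group, frame)
#' @param target_taxon label for the analyzed species in reports and FASTA
#'   headers
#' @param og_policy `"strict"` or `"prune"`: behaviour for group members
#'   missing from the loaded proteomes
#' @return a `run_config` list
#' @export
run_config <- function(fwd_min_bits = 0,
                       fwd_max_evalue = 1e-5,
                       rev_min_bits = 0,
                       max_overlap = 0L,
                       min_orf_coverage = 0.5,
                       frameshift_penalty = 15,
                       stop_penalty = 20,
                       gap_open = 11,
                       gap_extend = 1,
                       lambda = 0.267,
                       K = 0.041,
                       search_mode = c("exact", "heuristic"),
                       seed_len = 3L,
                       two_hit = TRUE,
                       two_hit_window = 40L,
                       ledger = c("section", "transcript"),
                       strict_brh = FALSE,
                       pseudocount = 1.0,
                       match_occupancy = 0.5,
                       stop_lod = -4,
                       isoform_identity = 0.95,
                       min_hit_aa = 10L,
                       max_hits_per_frame = 4L,
                       target_taxon = "target",
                       og_policy = c("strict", "prune")) {
  cfg <- list(
    fwd_min_bits = fwd_min_bits, fwd_max_evalue = fwd_max_evalue,
    rev_min_bits = rev_min_bits, max_overlap = as.integer(max_overlap),
    min_orf_coverage = min_orf_coverage,
    frameshift_penalty = frameshift_penalty, stop_penalty = stop_penalty,
    gap_open = gap_open, gap_extend = gap_extend, lambda = lambda, K = K,
    search_mode = match.arg(search_mode), seed_len = as.integer(seed_len),
    two_hit = isTRUE(two_hit), two_hit_window = as.integer(two_hit_window),
    ledger = match.arg(ledger), strict_brh = isTRUE(strict_brh),
    pseudocount = pseudocount, match_occupancy = match_occupancy,
    stop_lod = stop_lod, isoform_identity = isoform_identity,
    min_hit_aa = as.integer(min_hit_aa),
    max_hits_per_frame = as.integer(max_hits_per_frame),
    target_taxon = target_taxon, og_policy = match.arg(og_policy))
  stopifnot(cfg$fwd_max_evalue > 0, cfg$min_orf_coverage > 0,
            cfg$min_orf_coverage <= 1, cfg$max_overlap >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown
#' keys are an error.
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.null(x)) return(run_config())
  do.call(run_config, x[names(x) %in% names(formals(run_config))])
}
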