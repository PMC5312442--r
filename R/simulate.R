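# Synthetic reference sets and transcript libraries with planted ground
# truth: single-copy orthologs, inparalogs, isoforms, frameshift errors,
# chimeras and decoys, emulating the validation scenarios the pipeline is
# meant to handle. Generation is fully reproducible under the seed.

#' Simulation configuration
#'
#' @param seed RNG seed; generation is deterministic given the seed
#' @param n_ref_taxa number of reference species
#' @param n_ogs number of ortholog groups
#' @param gene_len length range of ancestral proteins (aa)
#' @param subst_prob per-site substitution probability on each branch
#'   (ancestor to each reference taxon, and ancestor to the target species)
#' @param inparalog_prob probability that a gene carries extra in-species
#'   copies in the target transcriptome
#' @param inparalog_max_copies maximum extra copies (uniform 1..max)
#' @param isoform_prob probability of an additional isoform transcript
#' @param isoform_deletion fraction of the protein deleted (centrally) in
#'   the isoform
#' @param frameshift_rate probability that a transcript carries one
#'   single-nucleotide insertion or deletion inside its coding region
#' @param n_decoy_proteins unrelated reference proteins placed in the
#'   proteomes but in no group (reverse-search decoys)
#' @param n_decoy_transcripts unrelated non-coding transcripts
#' @param missing_prob probability that a gene has no transcript
#' @param chimera_rate probability (per gene pair drawn) of a chimeric
#'   transcript fusing the coding regions of two genes
#' @param utr_len length range of random untranslated flanks (nt)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_ref_taxa = 4L, n_ogs = 20L,
                       gene_len = c(40L, 100L), subst_prob = 0.05,
                       inparalog_prob = 0, inparalog_max_copies = 2L,
                       isoform_prob = 0, isoform_deletion = 0.3,
                       frameshift_rate = 0, n_decoy_proteins = 10L,
                       n_decoy_transcripts = 5L, missing_prob = 0,
                       chimera_rate = 0, utr_len = c(10L, 60L)) {
  cfg <- list(seed = as.integer(seed), n_ref_taxa = as.integer(n_ref_taxa),
              n_ogs = as.integer(n_ogs), gene_len = as.integer(gene_len),
              subst_prob = subst_prob, inparalog_prob = inparalog_prob,
              inparalog_max_copies = as.integer(inparalog_max_copies),
              isoform_prob = isoform_prob,
              isoform_deletion = isoform_deletion,
              frameshift_rate = frameshift_rate,
              n_decoy_proteins = as.integer(n_decoy_proteins),
              n_decoy_transcripts = as.integer(n_decoy_transcripts),
              missing_prob = missing_prob, chimera_rate = chimera_rate,
              utr_len = as.integer(utr_len))
  probs <- c(cfg$subst_prob, cfg$inparalog_prob, cfg$isoform_prob,
             cfg$frameshift_rate, cfg$missing_prob, cfg$chimera_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$gene_len[1L] < 10L) stop("minimum gene length must be >= 10 aa")
  if (cfg$isoform_deletion <= 0 || cfg$isoform_deletion >= 1)
    stop("isoform_deletion must lie in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

.codons_of <- function() {
  if (is.null(.pkg_cache$codons_of)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons_of <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons_of
}

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

mutate_protein <- function(seq, p) {
  ch <- split_chars(seq)
  hit <- runif(length(ch)) < p
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA20, a), 1L), "")
  }
  paste(ch, collapse = "")
}

back_translate <- function(aa) {
  tab <- .codons_of()
  paste(vapply(split_chars(aa), function(a)
    sample(tab[[a]], 1L), ""), collapse = "")
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plant a single +-1 nt frameshift inside a coding sequence
plant_frameshift <- function(cds) {
  L <- nchar(cds)
  pos <- sample(seq(7L, L - 6L), 1L)
  if (runif(1L) < 0.5) {
    list(cds = paste0(substr(cds, 1L, pos),
                      sample(c("A", "C", "G", "T"), 1L),
                      substr(cds, pos + 1L, L)),
         pos = pos, size = 1L)
  } else {
    list(cds = paste0(substr(cds, 1L, pos - 1L), substr(cds, pos + 1L, L)),
         pos = pos - 1L, size = -1L)
  }
}

#' Generate a synthetic fixture
#'
#' Draws ancestral proteins, derives the reference taxa and the target
#' species by independent per-site substitutions, back-translates target
#' proteins with uniform synonymous codons, embeds the coding sequences in
#' random untranslated flanks on a random strand, and plants inparalogs,
#' isoforms, frameshifts, chimeras and decoys per configuration. Writes
#' the ortholog-group table, one proteome FASTA per reference taxon, the
#' transcript FASTA, and a ground-truth TSV.
#'
#' @param config a [sim_config()]
#' @param dir output directory
#' @return list with `og_table`, `proteomes` (named paths), `transcripts`
#'   (path), `truth` (data.frame and path), `config`
#' @export
sim_generate <- function(config = sim_config(), dir = tempfile("fixture")) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- sprintf("taxon%02d", seq_len(cfg$n_ref_taxa))
  ogs <- sprintf("OG%04d", seq_len(cfg$n_ogs))
  anc <- setNames(vapply(ogs, function(o)
    random_protein(sample(seq(cfg$gene_len[1L], cfg$gene_len[2L]), 1L)),
    ""), ogs)
  # reference proteomes and the group table
  prot_rows <- list(); og_rows <- list()
  for (tx in taxa) {
    for (o in ogs) {
      pid <- paste0(tx, "_", o)
      prot_rows[[pid]] <- data.frame(
        taxon = tx, protein_id = pid,
        sequence = mutate_protein(anc[[o]], cfg$subst_prob))
      og_rows[[length(og_rows) + 1L]] <-
        data.frame(og_id = o, taxon = tx, protein_id = pid)
    }
  }
  for (k in seq_len(cfg$n_decoy_proteins)) {
    tx <- taxa[(k - 1L) %% length(taxa) + 1L]
    pid <- sprintf("%s_decoy%03d", tx, k)
    prot_rows[[pid]] <- data.frame(
      taxon = tx, protein_id = pid,
      sequence = random_protein(
        sample(seq(cfg$gene_len[1L], cfg$gene_len[2L]), 1L)))
  }
  proteins <- do.call(rbind, prot_rows)
  # target transcripts with ground truth
  tr_rows <- list(); truth <- list()
  emit <- function(id, aa, og, class) {
    cds <- back_translate(aa)
    fs_pos <- integer(); fs_size <- integer()
    if (runif(1L) < cfg$frameshift_rate) {
      fs <- plant_frameshift(cds)
      cds <- fs$cds; fs_pos <- fs$pos; fs_size <- fs$size
    }
    cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1L))
    u5 <- random_nt(sample(seq(cfg$utr_len[1L], cfg$utr_len[2L]), 1L))
    u3 <- random_nt(sample(seq(cfg$utr_len[1L], cfg$utr_len[2L]), 1L))
    full <- paste0(u5, cds, u3)
    s <- nchar(u5); e <- s + nchar(cds) - 3L # coding interval, stop excluded
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      Lf <- nchar(full)
      full <- revcomp(full)
      tmp <- Lf - e; e <- Lf - s; s <- tmp
    }
    tr_rows[[id]] <<- data.frame(transcript_id = id, sequence = full)
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript_id = id, og_id = og, class = class, strand = strand,
      cds_start = s, cds_end = e,
      n_frameshifts = length(fs_pos),
      fs_pos = paste(fs_pos, collapse = ","),
      fs_size = paste(fs_size, collapse = ","), stringsAsFactors = FALSE)
  }
  target_aa <- setNames(vapply(ogs, function(o)
    mutate_protein(anc[[o]], cfg$subst_prob), ""), ogs)
  for (o in ogs) {
    if (runif(1L) < cfg$missing_prob) next
    emit(paste0("tr_", o), target_aa[[o]], o, "ortholog")
    if (runif(1L) < cfg$inparalog_prob) {
      for (k in seq_len(sample(cfg$inparalog_max_copies, 1L))) {
        emit(sprintf("tr_%s_para%d", o, k),
             mutate_protein(target_aa[[o]], cfg$subst_prob), o, "inparalog")
      }
    }
    if (runif(1L) < cfg$isoform_prob) {
      aa <- target_aa[[o]]
      n <- nchar(aa)
      ndel <- max(1L, round(cfg$isoform_deletion * n))
      from <- max(2L, (n - ndel) %/% 2L)
      iso <- paste0(substr(aa, 1L, from - 1L),
                    substr(aa, from + ndel, n))
      emit(paste0("tr_", o, "_iso"), iso, o, "isoform")
    }
  }
  if (cfg$chimera_rate > 0 && cfg$n_ogs >= 2L) {
    for (o in ogs) {
      if (runif(1L) < cfg$chimera_rate) {
        o2 <- sample(setdiff(ogs, o), 1L)
        id <- sprintf("tr_chimera_%s_%s", o, o2)
        cds1 <- back_translate(target_aa[[o]])
        cds2 <- back_translate(target_aa[[o2]])
        full <- paste0(random_nt(20L), cds1, random_nt(30L), cds2,
                       random_nt(20L))
        tr_rows[[id]] <- data.frame(transcript_id = id, sequence = full)
        s1 <- 20L
        s2 <- 20L + nchar(cds1) + 30L
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, og_id = o, class = "chimera", strand = "+",
          cds_start = s1, cds_end = s1 + nchar(cds1),
          n_frameshifts = 0L, fs_pos = "", fs_size = "",
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, og_id = o2, class = "chimera", strand = "+",
          cds_start = s2, cds_end = s2 + nchar(cds2),
          n_frameshifts = 0L, fs_pos = "", fs_size = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_len(cfg$n_decoy_transcripts)) {
    id <- sprintf("tr_decoy%03d", k)
    tr_rows[[id]] <- data.frame(transcript_id = id,
                                sequence = random_nt(sample(150:400, 1L)))
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = id, og_id = NA_character_, class = "decoy",
      strand = NA_character_, cds_start = NA_integer_,
      cds_end = NA_integer_, n_frameshifts = 0L, fs_pos = "", fs_size = "",
      stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, tr_rows)
  truth <- do.call(rbind, truth)
  # write everything in the formats the pipeline consumes
  og_tab <- do.call(rbind, og_rows)
  og_path <- file.path(dir, "og_table.tsv")
  utils::write.table(og_tab, og_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  prot_paths <- setNames(file.path(dir, paste0("rgs_", taxa, ".fa")), taxa)
  for (tx in taxa) {
    p <- proteins[proteins$taxon == tx, , drop = FALSE]
    write_fasta(p$sequence, p$protein_id, prot_paths[[tx]])
  }
  tr_path <- file.path(dir, "transcripts.fa")
  write_fasta(transcripts$sequence, transcripts$transcript_id, tr_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  list(og_table = og_path, proteomes = prot_paths, transcripts = tr_path,
       transcripts_df = transcripts, truth = truth,
       truth_path = truth_path, config = cfg, dir = dir)
}

#' Score assignments against planted ground truth
#'
#' A coding truth row is a true positive when its transcript is assigned
#' to its true group and a false negative otherwise; an assignment with no
#' matching truth row is a false positive; a decoy transcript with no
#' assignment is a true negative. Sensitivity is TP / (TP + FN); accuracy
#' is (TP + TN) / total rows.
#'
#' @param assignments assignments data.frame from [assign_all()]
#' @param truth ground-truth data.frame from [sim_generate()]
#' @return list of counts and rates, including per-class recall and
#'   redundancy diagnostics
#' @export
score_against_truth <- function(assignments, truth) {
  coding <- truth[!is.na(truth$og_id), , drop = FALSE]
  decoys <- truth[is.na(truth$og_id), , drop = FALSE]
  key <- function(t, o) paste(t, o, sep = "\r")
  have <- unique(key(assignments$transcript_id, assignments$og_id))
  tp_mask <- key(coding$transcript_id, coding$og_id) %in% have
  TP <- sum(tp_mask)
  FN <- sum(!tp_mask)
  truth_keys <- key(coding$transcript_id, coding$og_id)
  FP <- sum(!have %in% truth_keys)
  TN <- sum(!decoys$transcript_id %in% assignments$transcript_id)
  total <- nrow(truth)
  by_class <- vapply(split(tp_mask, coding$class), mean, 0)
  multi <- tapply(assignments$og_id, assignments$transcript_id,
                  function(x) length(unique(x)))
  # nt positions claimed twice within one transcript (should never happen)
  redundant_nt <- 0L
  for (tr in unique(assignments$transcript_id)) {
    a <- assignments[assignments$transcript_id == tr, , drop = FALSE]
    if (nrow(a) < 2L) next
    for (i in seq_len(nrow(a) - 1L)) {
      for (j in seq((i + 1L), nrow(a))) {
        redundant_nt <- redundant_nt +
          max(0L, min(a$nt_end[i], a$nt_end[j]) -
                max(a$nt_start[i], a$nt_start[j]))
      }
    }
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN, total = total,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       accuracy = (TP + TN) / total,
       class_recall = by_class,
       multi_og_transcripts = sum(multi > 1L),
       redundant_nt_positions = redundant_nt)
}
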