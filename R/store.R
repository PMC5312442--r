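# File-based run store: a directory of plain-text tables (TSV) and JSON
# metadata holding the ortholog set, the profile models, the transcript
# library and all persisted search results, so that assignment can be
# re-run under different parameters without repeating the searches.

STORE_SCHEMA_VERSION <- 1L

#' Create a run store
#' @param dir directory to create (must not contain a conflicting store)
#' @return the directory path, invisibly
#' @export
store_create <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = STORE_SCHEMA_VERSION,
               created_by = "orthomapr")
  jsonlite::write_json(meta, file.path(dir, "schema.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Open an existing run store
#'
#' Fails loudly when the store is missing or its schema version does not
#' match the version this build writes.
#' @param dir store directory
#' @return the directory path, invisibly
#' @export
store_open <- function(dir) {
  sf <- file.path(dir, "schema.json")
  if (!file.exists(sf)) stop("not a run store (no schema.json): ", dir)
  meta <- jsonlite::read_json(sf)
  if (!identical(as.integer(meta$schema_version), STORE_SCHEMA_VERSION)) {
    stop("store schema version ", meta$schema_version,
         " does not match supported version ", STORE_SCHEMA_VERSION)
  }
  invisible(dir)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = colClasses,
                    stringsAsFactors = FALSE)
}

#' Persist an ortholog set into a store
#' @param store store directory
#' @param set an `ortholog_set`
#' @export
store_write_ortholog_set <- function(store, set) {
  store_open(store)
  write_tsv(set$proteins, file.path(store, "proteins.tsv"))
  mem <- do.call(rbind, lapply(set$groups, function(g)
    cbind(og_id = g$og_id, g$members)))
  if (is.null(mem)) {
    mem <- data.frame(og_id = character(), taxon = character(),
                      protein_id = character())
  }
  write_tsv(mem, file.path(store, "groups.tsv"))
  jsonlite::write_json(list(set_id = set$set_id, taxa = set$taxa),
                       file.path(store, "set.json"), auto_unbox = TRUE)
  invisible(store)
}

#' Load the ortholog set from a store
#' @param store store directory
#' @return an `ortholog_set`
#' @export
store_read_ortholog_set <- function(store) {
  store_open(store)
  proteins <- read_tsv(file.path(store, "proteins.tsv"))
  mem <- read_tsv(file.path(store, "groups.tsv"))
  meta <- jsonlite::read_json(file.path(store, "set.json"),
                              simplifyVector = TRUE)
  groups <- lapply(split(mem, mem$og_id), function(g) {
    g <- g[order(g$taxon, g$protein_id), , drop = FALSE]
    list(og_id = g$og_id[1L],
         members = data.frame(taxon = g$taxon, protein_id = g$protein_id,
                              stringsAsFactors = FALSE))
  })
  og_of <- character()
  for (g in groups) og_of[g$members$protein_id] <- g$og_id
  structure(list(set_id = meta$set_id, groups = groups, proteins = proteins,
                 taxa = sort(unique(proteins$taxon)), og_of = og_of),
            class = "ortholog_set")
}

#' Persist profile models
#' @param store store directory
#' @param profiles named list of `profile_model`
#' @export
store_write_profiles <- function(store, profiles) {
  store_open(store)
  ser <- lapply(profiles, function(p) {
    list(og_id = p$og_id, nmatch = p$nmatch, match_cols = p$match_cols,
         emis = apply(p$emis, 1L, identity, simplify = FALSE),
         background = p$background, trans = p$trans)
  })
  jsonlite::write_json(ser, file.path(store, "profiles.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(store)
}

#' Load profile models
#' @param store store directory
#' @return named list of `profile_model`
#' @export
store_read_profiles <- function(store) {
  store_open(store)
  ser <- jsonlite::read_json(file.path(store, "profiles.json"),
                             simplifyVector = TRUE)
  lapply(ser, function(p) {
    emis <- if (is.list(p$emis)) do.call(rbind, p$emis) else
      matrix(p$emis, ncol = 20L)
    colnames(emis) <- AA20
    structure(list(og_id = p$og_id, nmatch = as.integer(p$nmatch),
                   match_cols = as.integer(p$match_cols), emis = emis,
                   background = p$background,
                   trans = lapply(p$trans, as.numeric)),
              class = "profile_model")
  })
}

#' Persist the transcript library and search results
#' @param store store directory
#' @param transcripts data.frame `transcript_id`, `sequence`
#' @param forward_hits,reverse_hits hit tables from the analyzer
#' @param config the [run_config()] the searches were run with
#' @export
store_write_hits <- function(store, transcripts, forward_hits,
                             reverse_hits, config) {
  store_open(store)
  write_tsv(transcripts, file.path(store, "transcripts.tsv"))
  write_tsv(forward_hits, file.path(store, "forward_hits.tsv"))
  write_tsv(reverse_hits, file.path(store, "reverse_hits.tsv"))
  jsonlite::write_json(unclass(as_run_config(config)),
                       file.path(store, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(store)
}

#' Load persisted transcripts and search results
#' @param store store directory
#' @return list `transcripts`, `forward`, `reverse`, `config`
#' @export
store_read_hits <- function(store) {
  store_open(store)
  fh <- file.path(store, "forward_hits.tsv")
  if (!file.exists(fh)) {
    stop("no hits found in store ", store,
         " (expected forward_hits.tsv); run the analyzer first")
  }
  fwd <- read_tsv(fh, colClasses = c(
    hit_id = "integer", og_id = "character", transcript_id = "character",
    frame = "character", strand = "character", bit_score = "numeric",
    evalue = "numeric", aa_start = "integer", aa_end = "integer",
    hmm_start = "integer", hmm_end = "integer", nt_start = "integer",
    nt_end = "integer", aa_seq = "character"))
  rev <- read_tsv(file.path(store, "reverse_hits.tsv"), colClasses = c(
    hit_id = "integer", target_protein_id = "character",
    raw_score = "numeric", bit_score = "numeric", evalue = "numeric",
    aln_len = "integer", rank = "integer"))
  tr <- read_tsv(file.path(store, "transcripts.tsv"),
                 colClasses = c(transcript_id = "character",
                                sequence = "character"))
  cfg <- jsonlite::read_json(file.path(store, "run.json"),
                             simplifyVector = TRUE)
  list(transcripts = tr, forward = fwd, reverse = rev,
       config = as_run_config(cfg))
}

#' Persist assignments and rejections
#' @param store store directory
#' @param assignments,rejections data.frames from [assign_all()]
#' @export
store_write_assignments <- function(store, assignments, rejections) {
  store_open(store)
  write_tsv(assignments, file.path(store, "assignments.tsv"))
  write_tsv(rejections, file.path(store, "rejections.tsv"))
  invisible(store)
}
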