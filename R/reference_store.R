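# Ingestion and validation of reference gene sets (proteomes) and
# ortholog-group membership tables -- the "manager" stage.

#' Parse an ortholog-group membership table
#'
#' Reads a tab-delimited table in the style of OrthoDB exports, one row per
#' group member. Duplicate rows are collapsed; assigning one protein to two
#' groups is an error.
#'
#' @param path tab-delimited file
#' @param column_map integer vector naming which columns hold `og_id`,
#'   `taxon` and `protein_id` (1-based)
#' @return list of ortholog groups, each `list(og_id, members)` where
#'   `members` is a data.frame with columns `taxon`, `protein_id`
#' @export
parse_og_table <- function(path,
                           column_map = c(og_id = 1L, taxon = 2L,
                                          protein_id = 3L)) {
  if (!file.exists(path)) stop("ortholog-group table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("ortholog-group table is empty: ", path)
    return(list())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(column_map)
  nf <- lengths(parts)
  if (any(nf < need)) {
    stop("malformed ortholog-group table row (fewer than ", need,
         " columns) at line ", which(nf < need)[1L])
  }
  df <- data.frame(
    og_id = vapply(parts, `[[`, "", column_map[["og_id"]]),
    taxon = vapply(parts, `[[`, "", column_map[["taxon"]]),
    protein_id = vapply(parts, `[[`, "", column_map[["protein_id"]]),
    stringsAsFactors = FALSE)
  df <- unique(df)
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup)) {
    confl <- df[df$protein_id %in% dup, , drop = FALSE]
    stop("protein(s) assigned to more than one ortholog group: ",
         paste(sprintf("%s (%s)", unique(confl$protein_id),
                       paste(confl$og_id, collapse = ",")), collapse = "; "))
  }
  df <- df[order(df$og_id, df$taxon, df$protein_id), , drop = FALSE]
  lapply(split(df, df$og_id), function(g) {
    list(og_id = g$og_id[1L],
         members = data.frame(taxon = g$taxon, protein_id = g$protein_id,
                              stringsAsFactors = FALSE))
  })
}

#' Load a reference proteome from amino-acid FASTA
#'
#' Headers are truncated at the first whitespace to obtain protein ids; the
#' full header is retained as description. Sequences are uppercased and a
#' single trailing stop symbol `*` is stripped; internal stops or characters
#' outside the 20 standard residues plus `X` are rejected.
#'
#' @param path FASTA file
#' @param taxon taxon name attached to every record
#' @return data.frame with columns `protein_id`, `taxon`, `sequence`,
#'   `length`, `description`
#' @export
load_rgs_fasta <- function(path, taxon) {
  aa <- Biostrings::readBStringSet(path) # byte-level: keep invalid codes visible
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (!all(ok)) {
    stop("invalid amino-acid characters in record(s): ",
         paste(ids[!ok], collapse = ", "))
  }
  data.frame(protein_id = ids, taxon = taxon, sequence = unname(seqs),
             length = nchar(unname(seqs)), description = unname(headers),
             stringsAsFactors = FALSE)
}

#' Assemble an ortholog set
#'
#' Joins parsed groups with loaded reference proteins. Under `"strict"`
#' policy a group member without a loaded protein is an error; under
#' `"prune"` such members are dropped (emptied groups removed) with a
#' warning. Same-taxon proteins within one group whose pairwise identity
#' exceeds `isoform_identity` are flagged as potential isoforms, since
#' near-identical reference sequences can make the reciprocal search return
#' the isoform that was not in the profile and so fail the criterion.
#'
#' @param groups output of [parse_og_table()]
#' @param proteins row-bound output of [load_rgs_fasta()] across taxa; all
#'   proteins (also those in no group) form the reverse-search database
#' @param policy `"strict"` or `"prune"`
#' @param set_id label for the set
#' @param isoform_identity identity threshold for the isoform warning
#' @param collapse_isoforms if `TRUE`, keep only the longest member per
#'   (taxon, group) among flagged isoform clusters
#' @return an `ortholog_set`: list with `set_id`, `groups`, `proteins`,
#'   `taxa`, `og_of` (named vector protein_id -> og_id)
#' @export
build_ortholog_set <- function(groups, proteins,
                               policy = c("strict", "prune"),
                               set_id = "default",
                               isoform_identity = 0.95,
                               collapse_isoforms = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(proteins), !anyDuplicated(proteins$protein_id))
  known <- proteins$protein_id
  kept <- list()
  for (g in groups) {
    present <- g$members$protein_id %in% known
    if (!all(present)) {
      missing <- g$members$protein_id[!present]
      if (policy == "strict") {
        stop("ortholog group ", g$og_id, " references unknown protein(s): ",
             paste(missing, collapse = ", "))
      }
      warning("dropping unresolved member(s) of ", g$og_id, ": ",
              paste(missing, collapse = ", "))
      g$members <- g$members[present, , drop = FALSE]
    }
    if (nrow(g$members)) kept[[g$og_id]] <- g
  }
  seq_of <- setNames(proteins$sequence, proteins$protein_id)
  # isoform screen: same-taxon members of one group at high identity
  for (nm in names(kept)) {
    g <- kept[[nm]]
    drop_ids <- character()
    for (tx in unique(g$members$taxon)) {
      ids <- g$members$protein_id[g$members$taxon == tx]
      if (length(ids) < 2L) next
      flagged <- FALSE
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq((i + 1L), length(ids))) {
          idy <- pairwise_identity(seq_of[[ids[i]]], seq_of[[ids[j]]])
          if (idy > isoform_identity) {
            flagged <- TRUE
            warning("potential isoforms in ", g$og_id, " (", tx, "): ",
                    ids[i], " vs ", ids[j],
                    sprintf(" (identity %.2f)", idy))
          }
        }
      }
      if (flagged && collapse_isoforms) {
        keep <- ids[which.max(nchar(seq_of[ids]))]
        drop_ids <- c(drop_ids, setdiff(ids, keep))
      }
    }
    if (length(drop_ids)) {
      g$members <- g$members[!g$members$protein_id %in% drop_ids, ,
                             drop = FALSE]
      kept[[nm]] <- g
    }
  }
  og_of <- character()
  for (g in kept) {
    og_of[g$members$protein_id] <- g$og_id
  }
  structure(list(set_id = set_id, groups = kept, proteins = proteins,
                 taxa = sort(unique(proteins$taxon)), og_of = og_of),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("ortholog_set '%s': %d groups, %d proteins (%d in groups), %d taxa\n",
              x$set_id, length(x$groups), nrow(x$proteins),
              length(x$og_of), length(x$taxa)))
  invisible(x)
}

#' Group membership lookup
#' @param set an `ortholog_set`
#' @param protein_id protein id(s)
#' @return og id per protein, `NA` for proteins in no group
#' @export
og_of <- function(set, protein_id) {
  out <- unname(set$og_of[protein_id])
  as.character(out)
}
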