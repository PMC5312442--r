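# Sequence alphabets, translation, and scoring-matrix helpers shared by the
# search and refinement modules.

# canonical residue order used by profile models (alphabetical 20 letters)
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (half-bit units) as shipped with Biostrings,
#' including the ambiguity columns `X` and `*`.
#' @return numeric matrix with amino-acid row/column names
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# map amino-acid characters to 0-based row indices of blosum62();
# anything unknown is scored through the X column
aa_to_mat_idx <- function(chars) {
  ab <- rownames(blosum62())
  i <- match(chars, ab)
  i[is.na(i)] <- match("X", ab)
  i - 1L
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# codon -> amino acid lookup over the 5-letter dna alphabet ACGTN.
# Codons containing N translate to 'X'; stops to '*'.
codon_table5 <- function() {
  if (is.null(.pkg_cache$codon5)) {
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T", "N")
    tab <- character(125)
    k <- 1L
    for (b1 in bases) for (b2 in bases) for (b3 in bases) {
      cd <- paste0(b1, b2, b3)
      tab[k] <- if (grepl("N", cd)) "X" else unname(gc[cd])
      k <- k + 1L
    }
    .pkg_cache$codon5 <- tab
  }
  .pkg_cache$codon5
}

nt_to_int5 <- function(s) {
  i <- match(split_chars(toupper(s)), c("A", "C", "G", "T", "N"))
  i[is.na(i)] <- 5L
  i - 1L
}

#' Translate a nucleotide string in frame +1
#'
#' Trailing 1-2 nt are dropped; stop codons render as `*`, codons containing
#' `N` as `X`.
#' @param nt nucleotide string over `ACGTN`
#' @return amino-acid string
#' @export
translate_nt <- function(nt) {
  v <- nt_to_int5(nt)
  ncod <- length(v) %/% 3L
  if (ncod == 0L) return("")
  v <- v[seq_len(3L * ncod)]
  idx <- 25L * v[seq(1L, by = 3L, length.out = ncod)] +
    5L * v[seq(2L, by = 3L, length.out = ncod)] +
    v[seq(3L, by = 3L, length.out = ncod)] + 1L
  paste(codon_table5()[idx], collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param nt nucleotide string over `ACGTN`
#' @return reverse-complemented string
#' @export
revcomp <- function(nt) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(split_chars(nt)), collapse = ""))
}

# pairwise identity of two unaligned aa sequences from a global alignment
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  al <- nw_align_cpp(aa_to_mat_idx(split_chars(a)),
                     aa_to_mat_idx(split_chars(b)),
                     blosum62(), gap_open, gap_extend)
  ca <- split_chars(a)[al$a_idx]
  cb <- split_chars(b)[al$b_idx]
  ok <- !is.na(al$a_idx) & !is.na(al$b_idx)
  if (!any(ok)) return(0)
  sum(ca[ok] == cb[ok]) / max(nchar(a), nchar(b))
}
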