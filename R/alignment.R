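#' In-frame codon alignment
#'
#' Container for an aligned set of coding sequences, stored as a taxa x
#' codon-column character matrix of codon triplets. Sequences must be equal
#' length, divisible by three, over the alphabet `A C G T - N`.
#'
#' @param sequences Named character vector of aligned CDS strings.
#' @return An object of class `codon_alignment` with elements `taxa`
#'   (character) and `codons` (character matrix, one triplet per cell).
#' @export
codon_alignment <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  if (lens[1] %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("unexpected characters in sequences: ", names(sequences)[bad][1])
  ncod <- lens[1] %/% 3L
  m <- matrix("", length(sequences), ncod,
              dimnames = list(names(sequences), NULL))
  for (i in seq_along(sequences)) {
    m[i, ] <- substring(sequences[i], 3L * seq_len(ncod) - 2L,
                        3L * seq_len(ncod))
  }
  structure(list(taxa = names(sequences), codons = m),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa,", ncol(x$codons),
      "codon columns\n")
  invisible(x)
}

#' Number of codon columns
#' @param aln A [codon_alignment].
#' @return Integer.
#' @export
n_codons <- function(aln) ncol(aln$codons)

#' Flatten a codon alignment back to sequence strings
#' @param aln A [codon_alignment].
#' @return Named character vector of aligned CDS strings.
#' @export
alignment_strings <- function(aln) {
  out <- apply(aln$codons, 1, paste0, collapse = "")
  names(out) <- aln$taxa
  out
}

#' Read / write codon alignments as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()].
#'
#' @param path File path.
#' @param aln A [codon_alignment] (for writing).
#' @return `read_codon_fasta` returns a [codon_alignment];
#'   `write_codon_fasta` returns `path` invisibly.
#' @export
read_codon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' @rdname read_codon_fasta
#' @export
write_codon_fasta <- function(aln, path) {
  ss <- Biostrings::DNAStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Translate a codon alignment to an amino-acid matrix
#'
#' Codons consisting of gaps translate to `-`; codons containing an
#' ambiguous base or a partial gap translate to `X`; stop codons translate
#' to `*`.
#'
#' @param aln A [codon_alignment].
#' @return Character matrix (taxa x residue columns) of one-letter codes.
#' @export
translate_alignment <- function(aln) {
  aa <- codon_aa()
  m <- aln$codons
  out <- matrix("X", nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "---"] <- "-"
  hit <- m %in% names(aa)
  out[hit] <- aa[m[hit]]
  out[m %in% c("TAA", "TAG", "TGA")] <- "*"
  out
}

#' Remove codon columns containing gaps or ambiguity
#'
#' The branch-site machinery operates on complete codon columns: any column
#' in which any taxon carries a gap character or an `N` is removed, as the
#' inference engine would otherwise see partially observed codons.
#'
#' @param aln A [codon_alignment].
#' @return List with `alignment` (cleaned [codon_alignment]) and
#'   `column_map` (integer vector mapping cleaned codon-column indices to
#'   original 1-based codon columns).
#' @export
strip_gap_columns <- function(aln) {
  m <- aln$codons
  bad <- apply(matrix(grepl("[-N]", m), nrow(m)), 2, any)
  keep <- which(!bad)
  if (length(keep) == 0L)
    stop("alignment empty after removing gapped/ambiguous columns")
  out <- aln
  out$codons <- m[, keep, drop = FALSE]
  list(alignment = out, column_map = keep)
}

# Map codon columns to 0-based state indices (61-state space); -1 for
# anything not a sense codon (should not survive strip_gap_columns()).
codon_states <- function(aln) {
  codons <- sense_codons()
  idx <- match(aln$codons, codons)
  idx[is.na(idx)] <- 0L
  matrix(as.integer(idx - 1L), nrow(aln$codons),
         dimnames = dimnames(aln$codons))
}

# Collapse alignment columns to unique site patterns with counts.
site_patterns <- function(states) {
  key <- apply(states, 2, paste0, collapse = ",")
  first <- !duplicated(key)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]),
       index = match(key, key[first]))
}
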