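# Validation of candidate positive sites against cDNA evidence: map each
# cDNA to the gene's CDS by local nucleotide alignment, keep cDNAs covering
# the site's codon, and declare the site valid iff the codon matches at
# least one covering cDNA exactly.

#' Map a cDNA onto a CDS
#'
#' Best local nucleotide alignment (match +2, mismatch -3, affine gaps
#' open 5 / extend 2), tried in both orientations; mappings below the score
#' or length floor are rejected.
#'
#' @param cds CDS nucleotide string (ungapped).
#' @param cdna cDNA nucleotide string.
#' @param min_score Minimum alignment score (default 40).
#' @param min_length Minimum aligned subject length in nt (default 30).
#' @return `NULL` if unmapped, else a list with `start`, `end` (1-based
#'   inclusive CDS interval), `strand` (`+`/`-`), and `aligned` (data
#'   frame: `cds_position`, `cds_base`, `cdna_base`; gaps as `-`).
#' @export
map_cdna <- function(cds, cdna, min_score = 40, min_length = 30) {
  stopifnot(nchar(cds) > 0, nchar(cdna) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  try_one <- function(query) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query),
      subject = Biostrings::DNAString(cds),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
  }
  fwd <- try_one(cdna)
  rvs <- try_one(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cdna))))
  strand <- if (Biostrings::score(fwd) >= Biostrings::score(rvs)) "+" else "-"
  pa <- if (strand == "+") fwd else rvs
  sub_rng <- pa@subject@range
  if (Biostrings::score(pa) < min_score ||
      Biostrings::width(sub_rng) < min_length) return(NULL)
  sub_al <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pat_al <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  pos <- integer(length(sub_al))
  cur <- Biostrings::start(sub_rng) - 1L
  for (i in seq_along(sub_al)) {
    if (sub_al[i] != "-") cur <- cur + 1L
    pos[i] <- cur  # for subject gaps, position of the last CDS base
  }
  aligned <- data.frame(cds_position = ifelse(sub_al == "-", NA, pos),
                        cds_base = sub_al, cdna_base = pat_al)
  list(start = Biostrings::start(sub_rng), end = Biostrings::end(sub_rng),
       strand = strand, aligned = aligned)
}

#' Validate one site against a set of cDNAs
#'
#' A cDNA covers the site iff its mapped CDS interval contains all three
#' codon positions. The site is `valid` iff at least one covering cDNA has
#' identical, ungapped bases at those positions; `invalid` iff covered but
#' never matched; `unmapped` iff no cDNA covers it.
#'
#' @param codon_index 1-based codon index of the site on the CDS.
#' @param cds CDS nucleotide string.
#' @param cdnas Character vector of cDNA sequences (named by cDNA id).
#' @param min_score,min_length Passed to [map_cdna()].
#' @return Object of class `site_validation`: `codon_index`,
#'   `n_cdnas_mapped`, `n_covering`, `n_identical`, `verdict`, and
#'   `per_cdna` (data frame: `cdna_id`, `mapped`, `covered`,
#'   `codon_identical`).
#' @export
validate_site <- function(codon_index, cds, cdnas, min_score = 40,
                          min_length = 30) {
  nt <- 3L * (codon_index - 1L) + 1:3
  stopifnot(max(nt) <= nchar(cds))
  ids <- if (is.null(names(cdnas))) paste0("cdna", seq_along(cdnas))
         else names(cdnas)
  rows <- lapply(seq_along(cdnas), function(i) {
    m <- map_cdna(cds, cdnas[i], min_score, min_length)
    if (is.null(m))
      return(data.frame(cdna_id = ids[i], mapped = FALSE, covered = FALSE,
                        codon_identical = FALSE))
    covered <- m$start <= nt[1] && m$end >= nt[3]
    identical <- FALSE
    if (covered) {
      al <- m$aligned[!is.na(m$aligned$cds_position) &
                        m$aligned$cds_position %in% nt, , drop = FALSE]
      identical <- nrow(al) == 3 &&
        all(al$cdna_base != "-") && all(al$cds_base == al$cdna_base)
      # an insertion inside the codon also breaks perfect alignment
      span <- range(which(!is.na(m$aligned$cds_position) &
                            m$aligned$cds_position %in% nt))
      if (identical && diff(span) != 2) identical <- FALSE
    }
    data.frame(cdna_id = ids[i], mapped = TRUE, covered = covered,
               codon_identical = identical)
  })
  per <- do.call(rbind, rows)
  n_cov <- sum(per$covered)
  verdict <- if (n_cov == 0) "unmapped"
             else if (any(per$codon_identical)) "valid" else "invalid"
  structure(list(codon_index = codon_index,
                 n_cdnas_mapped = sum(per$mapped), n_covering = n_cov,
                 n_identical = sum(per$codon_identical),
                 verdict = verdict, per_cdna = per),
            class = "site_validation")
}

#' @export
print.site_validation <- function(x, ...) {
  cat(sprintf("site_validation: codon %d -> %s (%d covering cDNAs)\n",
              x$codon_index, x$verdict, x$n_covering))
  invisible(x)
}

#' Summarize cDNA validation over a screen
#'
#' @param verdicts Character vector of per-site verdicts
#'   (`valid`/`invalid`/`unmapped`), optionally with a `gene` attribute-free
#'   companion vector via `genes`.
#' @param genes Optional gene id per site for the gene-level roll-up
#'   (a gene survives iff >= 1 of its sites is valid).
#' @return List with `n_total`, `n_mapped` (sites with a covering cDNA),
#'   `n_valid`, `n_invalid`, `coverage_pct` (= 100 n_mapped/n_total),
#'   `fpr_pct` (= 100 n_invalid/n_mapped, NA if nothing mapped), and
#'   `genes_surviving` (NA when `genes` is missing).
#' @export
validation_summary <- function(verdicts, genes = NULL) {
  stopifnot(all(verdicts %in% c("valid", "invalid", "unmapped")))
  n_total <- length(verdicts)
  n_valid <- sum(verdicts == "valid")
  n_invalid <- sum(verdicts == "invalid")
  n_mapped <- n_valid + n_invalid
  surviving <- NA_integer_
  if (!is.null(genes))
    surviving <- length(unique(genes[verdicts == "valid"]))
  list(n_total = n_total, n_mapped = n_mapped, n_valid = n_valid,
       n_invalid = n_invalid,
       coverage_pct = round(100 * n_mapped / n_total, 2),
       fpr_pct = if (n_mapped > 0) round(100 * n_invalid / n_mapped, 2)
                 else NA_real_,
       genes_surviving = surviving)
}
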