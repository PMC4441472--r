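# 1:1 ortholog calling by reciprocal best hits with an identity floor and
# longest-transcript selection. Similarity search is an affine-gap local
# protein alignment (BLOSUM62, gap open 11 / extend 1) with a minimum-score
# floor standing in for a search-tool E-value cutoff.

#' Keep the longest transcript per gene
#'
#' @param records Data frame with columns `species`, `gene_id`,
#'   `transcript_id`, `sequence`.
#' @return Data frame with exactly one row per (species, gene); length ties
#'   break lexicographically by `transcript_id`.
#' @export
select_longest_transcript <- function(records) {
  if (nrow(records) == 0) return(records)
  stopifnot(all(c("species", "gene_id", "transcript_id", "sequence")
                %in% names(records)), all(nchar(records$sequence) > 0))
  ord <- order(records$species, records$gene_id,
               -nchar(records$sequence), records$transcript_id)
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(r[, c("species", "gene_id")])
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Local alignment scores and identities of one query against a set of
# targets. Identity = matches / aligned columns (local alignment, so no
# end gaps) * 100.
protein_local_hits <- function(query_seq, target_seqs) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(target_seqs),
    subject = Biostrings::AAString(query_seq),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  data.frame(score = Biostrings::score(pa),
             identity = Biostrings::pid(pa, type = "PID1"))
}

#' Best local-alignment hit of a query protein
#'
#' Hits below the identity floor or the score floor are discarded before
#' ranking; ties on score break lexicographically by target `gene_id`.
#'
#' @param query One-row data frame (a protein record).
#' @param targets Data frame of candidate records (non-empty).
#' @param min_identity Identity floor in percent (default 60).
#' @param min_score Minimum alignment score (default 40; a stand-in for a
#'   BLAST E-value cutoff at desk scale).
#' @return One-row data frame with `gene_id`, `identity`, `score`, or
#'   `NULL` if no acceptable hit remains.
#' @export
best_hit <- function(query, targets, min_identity = 60, min_score = 40) {
  stopifnot(nrow(targets) >= 1)
  hits <- protein_local_hits(query$sequence, targets$sequence)
  hits$gene_id <- targets$gene_id
  hits <- hits[hits$identity >= min_identity & hits$score >= min_score, ,
               drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  hits <- hits[order(-hits$score, hits$gene_id), , drop = FALSE]
  hits[1, c("gene_id", "identity", "score")]
}

#' Reciprocal-best-hit 1:1 orthologs
#'
#' A pair (a, b) is retained iff b is a's best hit in `other` and a is b's
#' best hit in `reference`. Both proteomes should already be
#' transcript-selected ([select_longest_transcript()]).
#'
#' @param reference,other Protein record data frames (one species each).
#' @param min_identity,min_score Passed to [best_hit()].
#' @return Data frame with `reference_gene`, `other_gene`, `identity`,
#'   `score` (identity/score from the forward search).
#' @export
reciprocal_best_hits <- function(reference, other, min_identity = 60,
                                 min_score = 40) {
  empty <- data.frame(reference_gene = character(),
                      other_gene = character(), identity = numeric(),
                      score = numeric())
  if (nrow(reference) == 0 || nrow(other) == 0) return(empty)
  fwd <- lapply(seq_len(nrow(reference)), function(i)
    best_hit(reference[i, ], other, min_identity, min_score))
  rows <- list()
  back_cache <- new.env()
  for (i in seq_len(nrow(reference))) {
    h <- fwd[[i]]
    if (is.null(h)) next
    key <- h$gene_id
    bh <- if (!is.null(back_cache[[key]])) back_cache[[key]] else {
      b <- best_hit(other[other$gene_id == key, ][1, ], reference,
                    min_identity, min_score)
      back_cache[[key]] <- if (is.null(b)) NA else b
      back_cache[[key]]
    }
    if (length(bh) == 1 && is.na(bh)) next
    if (bh$gene_id == reference$gene_id[i]) {
      rows[[length(rows) + 1]] <- data.frame(
        reference_gene = reference$gene_id[i], other_gene = key,
        identity = h$identity, score = h$score)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
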