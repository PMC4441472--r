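# Sum-of-pairs (SP) penalty scoring of +/-15-residue alignment windows
# around candidate positive sites, with the general (-50) and individual
# (-15) threshold pass rule.

#' SP filter configuration
#'
#' @param window Focal residues collected per stream (default 15).
#' @param general_threshold Pass requires general score strictly greater
#'   (default -50).
#' @param individual_threshold Pass requires individual score strictly
#'   greater (default -15).
#' @param include_site Score the site column itself? Default `FALSE`: the
#'   site is the hypothesis under test, not alignment context.
#' @return Object of class `sp_config`.
#' @export
sp_config <- function(window = 15, general_threshold = -50,
                      individual_threshold = -15, include_site = FALSE) {
  stopifnot(window >= 1, is.finite(general_threshold),
            is.finite(individual_threshold))
  structure(list(window = as.integer(window),
                 general_threshold = general_threshold,
                 individual_threshold = individual_threshold,
                 include_site = include_site),
            class = "sp_config")
}

#' Extract the scoring windows around a site
#'
#' Walks alignment columns outward from the site until `window` focal-taxon
#' non-gap residues are collected per stream (or the alignment ends). All
#' intervening columns — including columns where the focal taxon is gapped —
#' belong to the window, so other-taxon gaps stay visible to scoring. The
#' site column itself is excluded.
#'
#' @param prot Protein alignment matrix (taxa x residue columns), e.g.
#'   from [translate_alignment()].
#' @param focal Focal taxon name.
#' @param site_column Residue column of the candidate site; the focal
#'   taxon must be ungapped there.
#' @param window Residues per stream.
#' @return List with `up`, `down` (column index vectors, in alignment
#'   order), `n_up`, `n_down` (focal residues found).
#' @export
extract_window <- function(prot, focal, site_column, window = 15) {
  stopifnot(focal %in% rownames(prot), site_column >= 1,
            site_column <= ncol(prot))
  if (prot[focal, site_column] == "-")
    stop("focal taxon is gapped at the site column")
  walk <- function(cols) {
    got <- 0L
    used <- integer(0)
    for (j in cols) {
      used <- c(used, j)
      if (prot[focal, j] != "-") got <- got + 1L
      if (got >= window) break
    }
    list(cols = as.integer(used), n = got)
  }
  up <- walk(rev(seq_len(site_column - 1L)))
  down <- walk(seq_len(ncol(prot) - site_column) + site_column)
  list(up = rev(up$cols), down = down$cols, n_up = up$n, n_down = down$n)
}

#' Pairwise SP penalty of two aligned windows
#'
#' Per column: identical residues score 0, differing residues `-S`, a
#' residue against a gap `-2S`, gap against gap 0 (shared gaps carry no
#' pairwise evidence).
#'
#' @param a,b Character vectors of residues (equal length; `-` = gap).
#' @param S Per-stream base penalty (`S = window / n` focal residues).
#' @return Total penalty (<= 0).
#' @export
pairwise_penalty <- function(a, b, S) {
  if (length(a) != length(b)) stop("window length mismatch")
  if (!length(a)) return(0)
  ga <- a == "-"
  gb <- b == "-"
  sum((!ga & !gb & a != b) * -S + xor(ga, gb) * -2 * S)
}

#' SP-score one candidate site
#'
#' The general score sums the up/downstream pairwise penalties over all
#' unordered taxon pairs and divides by N (the number of sequences); the
#' individual score sums the focal-versus-other penalties, unaveraged.
#' A site passes iff both scores are strictly greater than their
#' thresholds. Empty streams (site at a sequence edge) contribute 0.
#'
#' @param prot Protein alignment matrix (taxa x residue columns).
#' @param focal Focal taxon.
#' @param site_column Residue column of the site.
#' @param config An [sp_config()].
#' @return Object of class `sp_score`: `n_up`, `n_down`, `S_up`, `S_down`,
#'   `general_score`, `individual_score`, `pass`.
#' @export
score_site <- function(prot, focal, site_column, config = sp_config()) {
  if (nrow(prot) < 2) stop("need at least 2 sequences")
  win <- extract_window(prot, focal, site_column, config$window)
  if (config$include_site) win$down <- c(site_column, win$down)
  S_up <- if (win$n_up > 0) config$window / win$n_up else 0
  S_down <- if (win$n_down > 0) config$window / win$n_down else 0
  taxa <- rownames(prot)
  N <- length(taxa)
  pen <- function(t1, t2) {
    p <- 0
    if (win$n_up > 0)
      p <- p + pairwise_penalty(prot[t1, win$up], prot[t2, win$up], S_up)
    if (win$n_down > 0 || config$include_site)
      p <- p + pairwise_penalty(prot[t1, win$down], prot[t2, win$down],
                                S_down)
    p
  }
  general <- 0
  individual <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
    p <- pen(taxa[i], taxa[j])
    general <- general + p
    if (taxa[i] == focal || taxa[j] == focal) individual <- individual + p
  }
  general <- general / N
  structure(list(n_up = win$n_up, n_down = win$n_down, S_up = S_up,
                 S_down = S_down, general_score = general,
                 individual_score = individual,
                 pass = general > config$general_threshold &&
                        individual > config$individual_threshold),
            class = "sp_score")
}

#' @export
print.sp_score <- function(x, ...) {
  cat(sprintf("sp_score: general %.3f, individual %.3f -> %s\n",
              x$general_score, x$individual_score,
              if (x$pass) "pass" else "fail"))
  invisible(x)
}

#' SP-filter a table of candidate sites
#'
#' Scores every site against its gene's alignment and summarizes retention
#' per foreground species, reporting the misalignment false-positive rate
#' `FPR = 1 - retained/total`.
#'
#' @param sites Data frame with columns `gene`, `foreground`, `column`
#'   (codon/residue column, original coordinates).
#' @param alignments Named list of [codon_alignment] objects keyed by gene.
#' @param config An [sp_config()].
#' @return List with `sites` (input plus score fields and `pass`) and
#'   `summary` (per species: `total`, `retained`, `fpr_pct`). Sites whose
#'   gene alignment is missing or whose focal taxon is gapped at the site
#'   are reported with `pass = NA` and excluded from the summary.
#' @export
filter_sites <- function(sites, alignments, config = sp_config()) {
  n <- nrow(sites)
  out <- cbind(sites,
               data.frame(n_up = NA_integer_, n_down = NA_integer_,
                          general_score = NA_real_,
                          individual_score = NA_real_, pass = NA))
  for (k in seq_len(n)) {
    g <- sites$gene[k]
    if (is.null(alignments[[g]])) next
    prot <- translate_alignment(alignments[[g]])
    focal <- sites$foreground[k]
    if (!focal %in% rownames(prot)) next
    if (prot[focal, sites$column[k]] == "-") next
    sc <- score_site(prot, focal, sites$column[k], config)
    out$n_up[k] <- sc$n_up
    out$n_down[k] <- sc$n_down
    out$general_score[k] <- sc$general_score
    out$individual_score[k] <- sc$individual_score
    out$pass[k] <- sc$pass
  }
  scored <- out[!is.na(out$pass), , drop = FALSE]
  summary <- if (nrow(scored)) {
    agg <- stats::aggregate(pass ~ foreground, scored,
                     function(x) c(total = length(x), retained = sum(x)))
    data.frame(species = agg$foreground,
               total = agg$pass[, "total"],
               retained = agg$pass[, "retained"],
               fpr_pct = round(100 * (1 - agg$pass[, "retained"] /
                                        agg$pass[, "total"]), 2))
  } else data.frame(species = character(), total = integer(),
                    retained = integer(), fpr_pct = numeric())
  list(sites = out, summary = summary)
}

#' Misalignment false-positive rate from retention counts
#'
#' @param total Candidate sites before SP filtering.
#' @param retained Sites passing the SP filter.
#' @return Percentage `100 * (1 - retained/total)`, rounded to 2 decimals.
#' @export
misalignment_fpr <- function(total, retained) {
  stopifnot(all(retained <= total), all(total > 0))
  round(100 * (1 - retained / total), 2)
}
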