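# Orchestration of the full screen (branch-site test per foreground
# species -> SP filter -> cDNA validation) and the reporting arithmetic
# (group means, fold changes, overall retention).

#' Species-group design
#'
#' Two labeled groups (e.g. seasonal / non-seasonal breeders). Each species
#' is tested in turn as the foreground branch, with the species of the
#' opposite group as background — so a test tree holds the foreground
#' species plus the full opposite group.
#'
#' @param species Character vector of species names.
#' @param group Group label per species (exactly 2 distinct labels).
#' @param set_name Optional name for the species set.
#' @return Object of class `species_group_design` with a `tests` data
#'   frame (`foreground`, `group`, `background` list-column).
#' @export
species_group_design <- function(species, group, set_name = "set") {
  stopifnot(length(species) == length(group),
            length(unique(group)) == 2, !anyDuplicated(species))
  tests <- data.frame(foreground = species, group = group)
  tests$background <- lapply(seq_along(species), function(i)
    species[group != group[i]])
  structure(list(set_name = set_name, species = species, group = group,
                 tests = tests),
            class = "species_group_design")
}

#' @export
print.species_group_design <- function(x, ...) {
  cat("species_group_design '", x$set_name, "': ",
      paste(sprintf("%s (%s)", x$species, x$group), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Subset a codon alignment to a taxon set.
subset_alignment <- function(aln, taxa) {
  stopifnot(all(taxa %in% aln$taxa))
  out <- aln
  out$codons <- aln$codons[taxa, , drop = FALSE]
  out$taxa <- taxa
  out
}

# Codon index on the focal taxon's ungapped CDS for an alignment column.
cds_codon_index <- function(aln, taxon, column) {
  cods <- aln$codons[taxon, seq_len(column)]
  sum(cods != "---")
}

#' Run the full positive-selection screen
#'
#' For every species of the design as foreground: fits the branch-site
#' test to every gene (background = opposite group), applies the gene
#' thresholds with per-species BH-FDR, SP-filters the BEB sites, and, when
#' cDNAs are supplied, validates surviving sites against them. Per-gene
#' fit failures are recorded, not fatal. All stage tables can be persisted
#' as TSV; a rerun with `resume = TRUE` reloads finished per-species gene
#' stages instead of refitting.
#'
#' @param design A [species_group_design()].
#' @param alignments Named list of [codon_alignment] objects (all species).
#' @param tree An `ape::phylo` over all species (branch lengths required);
#'   pruned per test.
#' @param cdnas Optional data frame: `cdna_id`, `species`, `gene`,
#'   `sequence`.
#' @param p_threshold,q_threshold,beb_threshold Gene/site thresholds
#'   (defaults 0.01, 0.05, 0.95).
#' @param sp SP-filter configuration ([sp_config()]).
#' @param frequencies,n_starts,seed Passed to the fitting engine.
#' @param out_dir Optional directory for stage TSVs.
#' @param resume Reload persisted gene stages when present?
#' @return Object of class `screen_result`: `genes`, `sites` (with SP
#'   fields), `validations`, and `summary` (per species counts:
#'   `n_p001 >= n_fdr >= n_sp`, site counts and misalignment FPR).
#' @export
run_screen <- function(design, alignments, tree, cdnas = NULL,
                       p_threshold = 0.01, q_threshold = 0.05,
                       beb_threshold = 0.95, sp = sp_config(),
                       frequencies = "f3x4", n_starts = 2, seed = 1L,
                       out_dir = NULL, resume = FALSE) {
  stopifnot(inherits(design, "species_group_design"),
            inherits(tree, "phylo"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage_path <- function(name) file.path(out_dir, name)

  all_genes <- list()
  all_sites <- list()
  for (i in seq_len(nrow(design$tests))) {
    fg <- design$tests$foreground[i]
    taxa <- c(fg, design$tests$background[[i]])
    gene_file <- if (!is.null(out_dir))
      stage_path(sprintf("genes_%s.tsv", gsub("\\W", "_", fg))) else NULL
    site_file <- if (!is.null(out_dir))
      stage_path(sprintf("sites_%s.tsv", gsub("\\W", "_", fg))) else NULL
    if (resume && !is.null(gene_file) && file.exists(gene_file) &&
        file.exists(site_file)) {
      gtab <- utils::read.delim(gene_file)
      stab <- utils::read.delim(site_file)
    } else {
      message("screen: foreground ", fg, " (", ncol(alignments[[1]]$codons),
              " codon columns x ", length(alignments), " genes)")
      sub_alns <- lapply(alignments, subset_alignment, taxa = taxa)
      phy <- ape::keep.tip(tree, taxa)
      ltree <- labeled_tree(phy, fg)
      res <- screen_genes(sub_alns, ltree, p_threshold, q_threshold,
                          beb_threshold, frequencies, n_starts,
                          derive_seed(seed, i))
      gtab <- res$genes
      stab <- res$sites
      if (!is.null(gene_file)) {
        utils::write.table(gtab, gene_file, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        utils::write.table(stab, site_file, sep = "\t", row.names = FALSE,
                           quote = FALSE)
      }
    }
    gtab$foreground <- fg
    gtab$group <- design$tests$group[i]
    all_genes[[fg]] <- gtab
    all_sites[[fg]] <- stab
  }
  genes <- do.call(rbind, all_genes)
  rownames(genes) <- NULL
  sites <- do.call(rbind, all_sites)
  rownames(sites) <- NULL

  # SP filter over all candidate sites
  sub_for <- function(fg) {
    i <- match(fg, design$tests$foreground)
    c(fg, design$tests$background[[i]])
  }
  if (nrow(sites)) {
    sp_sites <- list()
    for (fg in unique(sites$foreground)) {
      alns <- lapply(alignments, subset_alignment, taxa = sub_for(fg))
      part <- filter_sites(sites[sites$foreground == fg, , drop = FALSE],
                           alns, sp)
      sp_sites[[fg]] <- part$sites
    }
    sites <- do.call(rbind, sp_sites)
    rownames(sites) <- NULL
  } else {
    sites$general_score <- numeric(0)
    sites$individual_score <- numeric(0)
    sites$pass <- logical(0)
  }

  # cDNA validation of SP-surviving sites
  validations <- data.frame(gene = character(), foreground = character(),
                            column = integer(), codon_index = integer(),
                            verdict = character())
  if (!is.null(cdnas) && nrow(sites)) {
    keep <- which(sites$pass %in% TRUE)
    rows <- lapply(keep, function(k) {
      fg <- sites$foreground[k]
      g <- sites$gene[k]
      pool <- cdnas[cdnas$species == fg & cdnas$gene == g, , drop = FALSE]
      aln <- alignments[[g]]
      cds <- gsub("-", "", paste0(aln$codons[fg, ], collapse = ""))
      ci <- cds_codon_index(aln, fg, sites$column[k])
      verdict <- if (nrow(pool) == 0) "unmapped" else {
        v <- validate_site(ci, cds,
                           stats::setNames(pool$sequence, pool$cdna_id))
        v$verdict
      }
      data.frame(gene = g, foreground = fg, column = sites$column[k],
                 codon_index = ci, verdict = verdict)
    })
    if (length(rows)) validations <- do.call(rbind, rows)
    rownames(validations) <- NULL
  }

  summary <- screen_summary(design, genes, sites)
  if (!is.null(out_dir)) {
    utils::write.table(sites, stage_path("sites_scored.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(summary, stage_path("summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (nrow(validations))
      utils::write.table(validations, stage_path("validations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(genes = genes, sites = sites, validations = validations,
                 summary = summary),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", nrow(x$genes), "gene tests,",
      nrow(x$sites), "candidate sites\n")
  print(x$summary)
  invisible(x)
}

# Per-species stage counts with the filter-monotonicity invariant
# n_sp <= n_fdr <= n_p001 by construction.
screen_summary <- function(design, genes, sites) {
  rows <- lapply(seq_len(nrow(design$tests)), function(i) {
    fg <- design$tests$foreground[i]
    g <- genes[genes$foreground == fg & genes$converged %in% TRUE, ,
               drop = FALSE]
    s <- sites[sites$foreground == fg & !is.na(sites$pass), , drop = FALSE]
    n_beb <- nrow(s)
    n_sp_sites <- sum(s$pass)
    data.frame(
      species = fg, group = design$tests$group[i],
      n_tested = sum(genes$foreground == fg),
      n_failed = sum(genes$foreground == fg & !genes$converged %in% TRUE),
      n_p001 = sum(g$pass_p), n_fdr = sum(g$pass),
      n_sp = length(unique(s$gene[s$pass])),
      sites_beb = n_beb, sites_sp = n_sp_sites,
      fpr_pct = if (n_beb > 0) misalignment_fpr(n_beb, n_sp_sites)
                else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means and cross-group fold change
#'
#' Arithmetic mean of a per-species count within each group, and the ratio
#' of the two group means.
#'
#' @param counts Data frame with a `group` column and the count column.
#' @param value Name of the count column.
#' @param numerator Group label used as the fold-change numerator; default
#'   is the group with the larger mean.
#' @return List with `means` (data frame `group`, `mean`) and `fold`
#'   (numerator mean / other mean; `NA` with a warning when the
#'   denominator mean is zero).
#' @export
group_means_and_fold <- function(counts, value = "n_fdr",
                                 numerator = NULL) {
  stopifnot("group" %in% names(counts), value %in% names(counts),
            length(unique(counts$group)) == 2)
  means <- stats::aggregate(counts[[value]],
                            by = list(group = counts$group), FUN = mean)
  names(means)[2] <- "mean"
  if (is.null(numerator))
    numerator <- means$group[which.max(means$mean)]
  num <- means$mean[means$group == numerator]
  den <- means$mean[means$group != numerator]
  fold <- if (den == 0) {
    warning("denominator group mean is zero; fold change undefined")
    NA_real_
  } else num / den
  list(means = means, fold = fold)
}

#' Overall site retention after SP filtering
#'
#' @param total Per-species candidate site counts (BEB > 0.95).
#' @param retained Per-species retained counts after SP filtering.
#' @return Percentage `100 * sum(retained) / sum(total)`, rounded to 2
#'   decimals.
#' @export
retention_overall <- function(total, retained) {
  stopifnot(length(total) == length(retained), all(retained <= total))
  round(100 * sum(retained) / sum(total), 2)
}
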