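#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study.
#
# Two breeding-strategy groups of three species each on a six-taxon tree.
# Eight genes: six evolve neutrally on every branch (omega2 = 1); two carry
# episodic positive selection (omega2 = 8) on a designated foreground
# lineage (one per group). One gene additionally receives misalignment
# corruption, and every gene gets error-free cDNA fragments for the
# reference species plus a proteome set for ortholog calling.
# Outputs under results/data/.

suppressMessages(library(posscreen))

seed <- 20240915
out <- "results/data"
dir.create(file.path(out, "alignments"), recursive = TRUE,
           showWarnings = FALSE)

species <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta")
group <- c("nonseasonal", "nonseasonal", "nonseasonal",
           "seasonal", "seasonal", "seasonal")
writeLines("species\tgroup", file.path(out, "design.tsv"))
write.table(data.frame(species, group), file.path(out, "design.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

tree <- "((alpha:0.08,beta:0.08):0.04,(gamma:0.1,delta:0.1):0.04,(epsilon:0.12,zeta:0.12):0.04);"
writeLines(tree, file.path(out, "species_tree.nwk"))

# per-gene settings: gene, foreground under selection (NA = null), omega2
plan <- data.frame(
  gene = sprintf("g%02d", 1:8),
  selected_fg = c("alpha", NA, NA, "epsilon", NA, NA, NA, NA),
  omega2 = c(8, 1, 1, 8, 1, 1, 1, 1))
write.table(plan, file.path(out, "gene_plan.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

truths <- list()
for (i in seq_len(nrow(plan))) {
  fg <- if (is.na(plan$selected_fg[i])) "alpha" else plan$selected_fg[i]
  tr <- sub(fg, paste0(fg, "#1"), tree, fixed = TRUE)
  cfg <- simulation_config(tr, n_codons = 450, omega2 = plan$omega2[i],
                           p0 = 0.6, p1 = 0.25,
                           seed = derive_seed(seed, i))
  sim <- simulate_alignment(cfg)
  aln <- sim$alignment
  if (plan$gene[i] == "g05") {
    # one gene carries a misaligned block on gamma
    cor <- corrupt_alignment(aln, corruption_spec(
      misalignment_windows = list(list(taxon = "gamma", start = 80,
                                       width = 30, mode = "shuffle")),
      seed = derive_seed(seed, 100 + i)))
    aln <- cor$alignment
  }
  write_codon_fasta(aln, file.path(out, "alignments",
                                   paste0(plan$gene[i], ".fa")))
  truths[[i]] <- cbind(gene = plan$gene[i], sim$truth)
}
write.table(do.call(rbind, truths), file.path(out, "site_truth.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# error-free cDNA fragments for every species
cdnas <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
  aln <- read_codon_fasta(file.path(out, "alignments",
                                    paste0(plan$gene[i], ".fa")))
  do.call(rbind, lapply(seq_along(species), function(s) {
    fr <- emit_cdnas(aln, species[s], n_fragments = 10,
                     span_range = c(40, 90),
                     seed = derive_seed(seed, 200 + 10 * i + s))
    cbind(fr$cdnas, gene = plan$gene[i])
  }))
}))
write.table(cdnas[, c("cdna_id", "taxon", "gene", "start_codon",
                      "end_codon", "sequence")],
            file.path(out, "cdnas.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)

# proteomes with known orthology for the RBH stage
pp <- emit_proteomes(n_species = 3, n_genes = 20, paralog_rate = 0.15,
                     identity_decay = 0.06,
                     seed = derive_seed(seed, 300))
write.table(pp$proteins, file.path(out, "proteomes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(pp$truth, file.path(out, "ortholog_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message("simulated ", nrow(plan), " genes (450 codons, 6 taxa), ",
        nrow(cdnas), " cDNA fragments, ",
        nrow(pp$proteins), " proteins -> ", out)
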