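#!/usr/bin/env Rscript
# Stage 2 — one-to-one ortholog calling.
#
# Reciprocal best hits of each non-reference proteome against the
# reference (sp1), after longest-transcript selection, with the 60%
# identity floor. Compares the calls against the generator's truth table.
# Outputs results/orthologs/orthologs.tsv.

suppressMessages(library(posscreen))

data_dir <- "results/data"
out <- "results/orthologs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prot <- read.delim(file.path(data_dir, "proteomes.tsv"))
truth <- read.delim(file.path(data_dir, "ortholog_truth.tsv"))

ref <- select_longest_transcript(prot[prot$species == "sp1", ])
tabs <- list()
for (sp in setdiff(unique(prot$species), "sp1")) {
  oth <- select_longest_transcript(prot[prot$species == sp, ])
  pairs <- reciprocal_best_hits(ref, oth)
  pairs$other_species <- sp
  # check against truth: a call is correct when both genes descend from
  # the same ancestral gene and neither is a paralog copy
  anc <- function(g) truth$ancestor_gene[match(g, truth$gene_id)]
  par <- function(g) truth$is_paralog[match(g, truth$gene_id)]
  pairs$correct <- anc(pairs$reference_gene) == anc(pairs$other_gene) &
    !par(pairs$reference_gene) & !par(pairs$other_gene)
  message(sp, ": ", nrow(pairs), " RBH pairs, ",
          sum(pairs$correct), " correct, min identity ",
          round(min(pairs$identity), 1), "%")
  tabs[[sp]] <- pairs
}
all_pairs <- do.call(rbind, tabs)
write.table(all_pairs, file.path(out, "orthologs.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("precision: ",
        round(mean(all_pairs$correct), 3), " over ",
        nrow(all_pairs), " pairs -> ", out)
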