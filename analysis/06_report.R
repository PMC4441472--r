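#!/usr/bin/env Rscript
# Stage 6 — summary report.
#
# Rolls the stage outputs up into the per-species / per-group summary
# (gene counts under successive filters, site retention, misalignment
# FPR, group means and the seasonal/non-seasonal fold change), and
# reproduces the same arithmetic over the published per-species count
# tables shipped with the package. Outputs under results/report/.

suppressMessages(library(posscreen))

out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read.delim("results/screen/genes.tsv")
scored <- read.delim("results/spfilter/sites_scored.tsv")
design_tab <- read.delim("results/data/design.tsv")

rows <- lapply(seq_len(nrow(design_tab)), function(i) {
  fg <- design_tab$species[i]
  g <- genes[genes$foreground == fg & genes$converged, ]
  s <- scored[scored$foreground == fg & !is.na(scored$pass), ]
  data.frame(species = fg, group = design_tab$group[i],
             n_p001 = sum(g$pass_p), n_fdr = sum(g$pass),
             n_sp = length(unique(s$gene[s$pass])),
             sites_beb = nrow(s), sites_sp = sum(s$pass),
             fpr_pct = if (nrow(s)) misalignment_fpr(nrow(s), sum(s$pass))
                       else NA)
})
summary <- do.call(rbind, rows)
write.table(summary, file.path(out, "summary_by_species.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("synthetic screen, per species:")
print(summary, row.names = FALSE)

gm <- group_means_and_fold(summary, value = "n_fdr")
message("group means (FDR-passing genes): ",
        paste(gm$means$group, round(gm$means$mean, 2), collapse = ", "),
        "; fold = ", round(gm$fold, 2))
if (sum(summary$sites_beb) > 0)
  message("overall SP retention: ",
          retention_overall(summary$sites_beb, summary$sites_sp), "%")

# the same arithmetic over the published count tables
pub_sites <- published_site_counts()
pub_genes <- published_gene_counts()
pub <- data.frame(
  quantity = c("overall_sp_retention_pct", "close_fold_change",
               "distant_fold_change", "close_nonseasonal_fdr_mean",
               "misalignment_fpr_min_pct", "misalignment_fpr_max_pct",
               "validated_gene_count"),
  value = c(retention_overall(pub_sites$sites_beb, pub_sites$sites_sp),
            group_means_and_fold(pub_genes[pub_genes$set == "Close", ],
                                 numerator = "seasonal")$fold,
            group_means_and_fold(pub_genes[pub_genes$set == "Distant", ],
                                 numerator = "seasonal")$fold,
            mean(pub_genes$n_fdr[pub_genes$set == "Close" &
                                   pub_genes$group == "non-seasonal"]),
            min(misalignment_fpr(pub_sites$sites_beb, pub_sites$sites_sp)),
            max(misalignment_fpr(pub_sites$sites_beb, pub_sites$sites_sp)),
            nrow(published_validated_genes())))
write.table(pub, file.path(out, "published_arithmetic.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("published-count arithmetic:")
print(pub, row.names = FALSE)
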